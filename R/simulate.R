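#' Configuration for the paired-region generator
#'
#' Defines the study conditions emulated by [simulate_paired_regions()]:
#' multi-donor laminar strips for an agranular "region A" (no granular L4
#' band, L6 split into L6a/L6b) and a granular six-layer "region B", with
#' matched single-nucleus profiles per donor, a rare deep-L5 cell type
#' present in region A only, and a set of technical genes that track library
#' size.
#'
#' @param n_donors number of donors; each donor contributes one capture area
#'   per region and one nucleus pool.
#' @param n_genes total genes.
#' @param layers_A ordered band labels for region A.
#' @param layers_B ordered band labels for region B.
#' @param spots_per_band spots per band per capture area.
#' @param markers_per_layer genes in each band/program marker set.
#' @param marker_lfc log2 fold elevation of a marker inside its band/type.
#' @param rare_type_prevalence nucleus-level prevalence of the rare deep-L5
#'   type (a von Economo neuron stand-in), in (0, 0.5).
#' @param libsize_lognormal `c(mu, sigma)` of the per-observation lognormal
#'   library-size factor.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param donor_sd standard deviation of the per-donor, per-gene lognormal
#'   effect.
#' @param type_profile_sd standard deviation of the per-type broad
#'   (transcriptome-wide) lognormal expression profile; cell types differ
#'   across most genes, not only at their markers.
#' @param ambient_scale off-context rate multiplier of the region-A-specific
#'   deep-L5 and rare programs: ambient background in region-A spots and in
#'   all nuclei; region B never expresses these transcripts.
#' @param flat_genes number of reserved genes with no type, band, or marker
#'   structure (library size and donor effects only); the spatially flat
#'   reference set.
#' @param technical_factor_genes number of genes whose rate scales with
#'   library size a second time (planting a library-size-driven factor).
#' @param n_nuclei_per_donor nuclei sampled per donor.
#' @param seed integer seed; the single RNG stream for all draws.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_donors = 10, n_genes = 2000,
                       layers_A = c("L1", "L2", "L3", "L5", "L6a", "L6b", "WM"),
                       layers_B = c("L1", "L2", "L3", "L4", "L5", "L6", "WM"),
                       spots_per_band = 20, markers_per_layer = 100,
                       marker_lfc = 2, rare_type_prevalence = 0.03,
                       libsize_lognormal = c(mu = 0, sigma = 0.35),
                       nb_dispersion = 0.5, donor_sd = 0.15,
                       type_profile_sd = 0.4, ambient_scale = 0.02,
                       flat_genes = 300, technical_factor_genes = 50,
                       n_nuclei_per_donor = 400, seed = 7) {
  cfg <- list(
    n_donors = n_donors, n_genes = n_genes, layers_A = layers_A,
    layers_B = layers_B, spots_per_band = spots_per_band,
    markers_per_layer = markers_per_layer, marker_lfc = marker_lfc,
    rare_type_prevalence = rare_type_prevalence,
    libsize_lognormal = libsize_lognormal, nb_dispersion = nb_dispersion,
    donor_sd = donor_sd, type_profile_sd = type_profile_sd,
    ambient_scale = ambient_scale, flat_genes = flat_genes,
    technical_factor_genes = technical_factor_genes,
    n_nuclei_per_donor = n_nuclei_per_donor, seed = seed
  )
  if (length(layers_A) < 3 || length(layers_B) < 3) {
    stop("each region needs at least 3 bands")
  }
  if (rare_type_prevalence <= 0 || rare_type_prevalence >= 0.5) {
    stop("rare_type_prevalence must be in (0, 0.5)")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (donor_sd < 0) stop("donor_sd must be >= 0")
  programs <- sim_programs(cfg)
  n_special <- 15 + (length(programs) + 2) * markers_per_layer +
    technical_factor_genes + flat_genes
  if (n_special > n_genes) {
    stop(sprintf(
      "infeasible config: %d marker/technical/mito/flat genes exceed n_genes = %d",
      n_special, n_genes
    ))
  }
  structure(cfg, class = "sim_config")
}

# Band -> expression program mapping. Region B's merged L6 band expresses
# both sub-band programs; every other band has a program of its own.
sim_band_programs <- function(band) {
  if (band == "L6") c("L6a", "L6b") else band
}

sim_programs <- function(cfg) {
  unique(unlist(lapply(union(cfg$layers_A, cfg$layers_B), sim_band_programs)))
}

#' Simulate paired SRT regions with matched single-nucleus data
#'
#' Counts are drawn negative-binomially with per-gene base rates multiplied
#' by a cell-type (or band-aligned) broad expression profile, band/type
#' marker effects, a per-donor lognormal effect, and a per-observation
#' library-size factor. Region A lacks the granular band and carries the
#' rare type's program (and an associated deep-L5 program) confined to the
#' deeper half of its L5 band, with a low ambient background across region-A
#' data; region B never expresses these transcripts. The rare type is
#' modeled as an L5 subclass: it shares the L5 cell type's broad profile and
#' band program on top of its own markers. A designated set of technical
#' genes scales with library size a second time, and a reserved block of
#' flat genes carries no spatial or type structure. The same seed reproduces
#' identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `spatial` (list `A`, `B` of `spatial_sample`
#'   lists, one per donor), `nuclei` (a `count_assay` with donor/sex/
#'   cell-type metadata), and `truth` (marker sets, technical/mito/flat gene
#'   ids, type-to-band map, the config).
#' @export
simulate_paired_regions <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  G <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(G))
  programs <- sim_programs(cfg)

  # disjoint special gene sets laid out over the gene index
  idx <- 1L
  take <- function(n) {
    out <- seq.int(idx, idx + n - 1L)
    idx <<- idx + n
    out
  }
  mito_idx <- take(15L)
  program_idx <- stats::setNames(
    lapply(programs, function(p) take(cfg$markers_per_layer)), programs
  )
  deep_idx <- take(cfg$markers_per_layer)
  rare_idx <- take(cfg$markers_per_layer)
  tech_idx <- take(cfg$technical_factor_genes)
  flat_idx <- take(cfg$flat_genes)

  base <- stats::rgamma(G, shape = 0.8, rate = 1) + 0.05
  base[mito_idx] <- base[mito_idx] * 3
  # marker genes are detectable by construction: real laminar and cell-type
  # markers sit in the expressed part of the transcriptome
  marker_all <- c(unlist(program_idx), deep_idx, rare_idx)
  base[marker_all] <- pmax(base[marker_all], stats::median(base))
  base <- base / sum(base) * 1500

  donors <- sprintf("d%02d", seq_len(cfg$n_donors))
  sex <- ifelse(seq_len(cfg$n_donors) %% 2 == 1, "M", "F")
  names(sex) <- donors
  donor_fac <- matrix(
    exp(stats::rnorm(G * cfg$n_donors, 0, cfg$donor_sd)),
    nrow = G, dimnames = list(gene_ids, donors)
  )

  # broad per-type profiles; the rare type is an L5 subclass (same broad
  # profile); the granular band of region B gets a profile of its own; flat
  # genes are profile-free everywhere
  cell_types <- paste0("CT_", cfg$layers_A)
  prof_cols <- c(cell_types, "VEN", setdiff(cfg$layers_B, cfg$layers_A))
  prof <- matrix(
    exp(stats::rnorm(G * length(prof_cols), 0, cfg$type_profile_sd)),
    nrow = G, dimnames = list(gene_ids, prof_cols)
  )
  prof[, "VEN"] <- prof[, "CT_L5"]
  prof[flat_idx, ] <- 1

  band_profile <- function(band) {
    if (band %in% cfg$layers_A) return(prof[, paste0("CT_", band)])
    pp <- sim_band_programs(band)
    if (all(paste0("CT_", pp) %in% colnames(prof))) {
      # merged band: geometric mean of its sub-band types
      out <- rep(1, G)
      for (p in pp) out <- out * prof[, paste0("CT_", p)]
      out^(1 / length(pp))
    } else {
      prof[, band]
    }
  }

  mult <- 2^cfg$marker_lfc
  amb <- cfg$ambient_scale
  mu_ls <- cfg$libsize_lognormal[[1]]
  sd_ls <- cfg$libsize_lognormal[[2]]
  size <- 1 / cfg$nb_dispersion

  gene_meta <- data.frame(
    gene_id = gene_ids,
    symbol = gene_ids,
    mito = seq_len(G) %in% mito_idx,
    row.names = gene_ids
  )

  band_layout <- function(bands) {
    two_col <- cfg$spots_per_band %% 2 == 0
    per_col <- if (two_col) cfg$spots_per_band / 2 else cfg$spots_per_band
    out <- do.call(rbind, lapply(seq_along(bands), function(b) {
      ncols <- if (two_col) 2L else 1L
      data.frame(
        band = bands[b],
        x = rep((b - 1L) * ncols + seq_len(ncols), each = per_col),
        y = rep(seq_len(per_col), times = ncols),
        local_col = rep(seq_len(ncols), each = per_col)
      )
    }))
    out$deep <- if (two_col) out$local_col == 2L else out$y > per_col / 2
    out
  }

  draw_counts <- function(rate_mat) {
    n <- ncol(rate_mat)
    cm <- matrix(
      stats::rnbinom(G * n, mu = rate_mat, size = size),
      nrow = G
    )
    methods::as(methods::as(Matrix::Matrix(cm, sparse = TRUE),
                            "CsparseMatrix"), "generalMatrix")
  }

  make_region <- function(region, bands) {
    lay <- band_layout(bands)
    n <- nrow(lay)
    lapply(donors, function(d) {
      L <- stats::rlnorm(n, mu_ls, sd_ls)
      M <- matrix(1, G, n)
      for (b in unique(lay$band)) {
        cols <- which(lay$band == b)
        bp <- band_profile(b)
        M[, cols] <- bp
        for (p in sim_band_programs(b)) {
          M[program_idx[[p]], cols] <- mult * bp[program_idx[[p]]]
        }
      }
      # region-A-specific programs: ambient in A, absent in B
      M[deep_idx, ] <- if (region == "A") amb else 0
      M[rare_idx, ] <- if (region == "A") amb else 0
      if (region == "A" && "L5" %in% lay$band) {
        deep_cols <- which(lay$band == "L5" & lay$deep)
        M[deep_idx, deep_cols] <- mult * prof[deep_idx, "VEN"]
        M[rare_idx, deep_cols] <- mult * prof[rare_idx, "VEN"]
      }
      rate <- (base * donor_fac[, d]) * M
      rate <- sweep(rate, 2, L, `*`)
      rate[tech_idx, ] <- sweep(rate[tech_idx, , drop = FALSE], 2, L, `*`)
      counts <- draw_counts(rate)
      ids <- sprintf("%s_%s_s%03d", region, d, seq_len(n))
      assay <- count_assay(
        counts, gene_ids = gene_ids, obs_ids = ids, gene_meta = gene_meta,
        obs_meta = data.frame(
          obs_id = ids, donor = d, sample = paste(region, d, sep = "_"),
          region = region, band = lay$band,
          deep_L5 = lay$band == "L5" & lay$deep,
          row.names = ids
        )
      )
      spatial_sample(assay, xy = cbind(lay$x, lay$y), in_tissue = TRUE,
                     sample_id = paste(region, d, sep = "_"), donor = d,
                     domain = lay$band)
    })
  }

  spatial <- list(A = make_region("A", cfg$layers_A),
                  B = make_region("B", cfg$layers_B))

  # nuclei: one pool per donor; layer-aligned types plus the rare type
  nuc_list <- lapply(donors, function(d) {
    n <- cfg$n_nuclei_per_donor
    n_rare <- max(1L, round(cfg$rare_type_prevalence * n))
    n_rest <- n - n_rare
    per <- rep(n_rest %/% length(cell_types), length(cell_types))
    extra <- n_rest %% length(cell_types)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    types <- c(rep(cell_types, per), rep("VEN", n_rare))
    L <- stats::rlnorm(n, mu_ls, sd_ls)
    M <- matrix(1, G, n)
    M[c(deep_idx, rare_idx), ] <- amb
    for (i in seq_along(cell_types)) {
      cols <- which(types == cell_types[i])
      M[, cols] <- prof[, cell_types[i]]
      for (p in sim_band_programs(cfg$layers_A[i])) {
        M[program_idx[[p]], cols] <- mult * prof[program_idx[[p]], cell_types[i]]
      }
      M[c(deep_idx, rare_idx), cols] <- amb
    }
    rare_cols <- which(types == "VEN")
    if (length(rare_cols)) {
      M[, rare_cols] <- prof[, "VEN"]
      M[program_idx[["L5"]], rare_cols] <-
        mult * prof[program_idx[["L5"]], "VEN"]
      M[deep_idx, rare_cols] <- mult * prof[deep_idx, "VEN"]
      M[rare_idx, rare_cols] <- mult * prof[rare_idx, "VEN"]
    }
    rate <- (base * donor_fac[, d]) * M
    rate <- sweep(rate, 2, L, `*`)
    rate[tech_idx, ] <- sweep(rate[tech_idx, , drop = FALSE], 2, L, `*`)
    ids <- sprintf("N_%s_n%04d", d, seq_len(n))
    list(counts = draw_counts(rate), ids = ids, types = types)
  })
  nuc_counts <- do.call(cbind, lapply(nuc_list, `[[`, "counts"))
  nuc_ids <- unlist(lapply(nuc_list, `[[`, "ids"))
  nuc_types <- unlist(lapply(nuc_list, `[[`, "types"))
  nuc_donor <- rep(donors, each = cfg$n_nuclei_per_donor)
  nuclei <- count_assay(
    nuc_counts, gene_ids = gene_ids, obs_ids = nuc_ids, gene_meta = gene_meta,
    obs_meta = data.frame(
      obs_id = nuc_ids, donor = nuc_donor, sample = nuc_donor,
      sex = sex[nuc_donor], cell_type = nuc_types, row.names = nuc_ids
    )
  )

  marker_sets <- c(
    lapply(program_idx, function(i) gene_ids[i]),
    list(deep_L5 = gene_ids[deep_idx], rare = gene_ids[rare_idx])
  )
  truth <- list(
    marker_sets = marker_sets,
    band_marker_sets = marker_sets[intersect(names(marker_sets), programs)],
    rare_type = "VEN", cell_types = c(cell_types, "VEN"),
    type_home_band = stats::setNames(cfg$layers_A, cell_types),
    technical_genes = gene_ids[tech_idx],
    mito_genes = gene_ids[mito_idx],
    flat_genes = gene_ids[flat_idx],
    config = cfg
  )
  list(spatial = spatial, nuclei = nuclei, truth = truth)
}

#' Simulate per-cell smFISH measurement tables
#'
#' Emulates single-molecule FISH quantification output: per-cell planar
#' coordinates, cell area, and per-gene copy counts and signal intensities.
#' An anchor gene is elevated only inside a horizontal band of the plane
#' (two elevated subpopulations plus the off state, so a k=3 gate splits off
#' the non-expressors); each target gene is a two-component copy-count
#' mixture with the expressor state drawn independently of position. Copy
#' counts scale with relative cell area, so area normalization recovers the
#' component rates; intensity is correlated with copy count.
#'
#' @param n_cells number of cells.
#' @param expressor_fraction probability a cell expresses a target gene
#'   (scalar or per-gene vector).
#' @param mu_off,mu_on Poisson copy-count rates of the two components;
#'   `mu_on > mu_off >= 0`.
#' @param area_lognormal `c(meanlog, sdlog)` of the cell-area distribution.
#' @param anchor_band `c(ymin, ymax)` as fractions of the plane height; the
#'   anchor gene is elevated only inside it.
#' @param genes target gene names.
#' @param anchor_gene anchor gene name.
#' @param seed integer seed.
#' @return list with `cells` (the measurement data.frame) and `truth`
#'   (logical expressor matrix and anchor band membership).
#' @export
simulate_smfish <- function(n_cells = 2000, expressor_fraction = 0.3,
                            mu_off = 0.5, mu_on = 20,
                            area_lognormal = c(meanlog = log(80), sdlog = 0.3),
                            anchor_band = c(0.35, 0.65),
                            genes = c("SULF2", "POU3F1", "GABRQ"),
                            anchor_gene = "PCP4", seed = 1) {
  if (!(mu_on > mu_off && mu_off >= 0)) stop("need mu_on > mu_off >= 0")
  set.seed(seed)
  frac <- rep_len(expressor_fraction, length(genes))
  x <- stats::runif(n_cells, 0, 1000)
  y <- stats::runif(n_cells, 0, 1000)
  area <- stats::rlnorm(n_cells, area_lognormal[[1]], area_lognormal[[2]])
  rel_area <- area / exp(area_lognormal[[1]])

  cells <- data.frame(cell_id = sprintf("c%05d", seq_len(n_cells)),
                      x = x, y = y, area = area)
  intensity_of <- function(copies) {
    pmax(0, copies * 3 * (1 + stats::rnorm(n_cells, 0, 0.1)) +
           abs(stats::rnorm(n_cells, 0, 0.5)))
  }

  in_band <- y >= anchor_band[1] * 1000 & y <= anchor_band[2] * 1000
  sub <- sample(c(0.6, 1.4), n_cells, replace = TRUE)
  anchor_mu <- ifelse(in_band, mu_on * sub, mu_off)
  anchor_copies <- stats::rpois(n_cells, anchor_mu * rel_area)
  cells[[paste0(anchor_gene, "_copies")]] <- anchor_copies
  cells[[paste0(anchor_gene, "_intensity")]] <- intensity_of(anchor_copies)

  expressor <- matrix(FALSE, n_cells, length(genes),
                      dimnames = list(cells$cell_id, genes))
  for (j in seq_along(genes)) {
    on <- stats::runif(n_cells) < frac[j]
    expressor[, j] <- on
    mu <- ifelse(on, mu_on, mu_off)
    copies <- stats::rpois(n_cells, mu * rel_area)
    cells[[paste0(genes[j], "_copies")]] <- copies
    cells[[paste0(genes[j], "_intensity")]] <- intensity_of(copies)
  }
  list(cells = cells,
       truth = list(expressor = expressor, anchor_in_band = in_band,
                    genes = genes, anchor_gene = anchor_gene))
}
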