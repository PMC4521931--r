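# Sub-seeds derived from the one user-facing seed so each generator can be
# re-run independently yet reproducibly.
derive_seed <- function(seed, stage) {
  offsets <- c(evidence = 1L, peaklist = 2L, annotations = 3L)
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]]) %% (2^31 - 1))
}

#' Configuration for the synthetic SILAC experiment generator
#'
#' Defaults emulate a two-replicate, three-channel SILAC study of ~2000
#' quantifiable proteins: a Gaussian log2-ratio background, a 6% regulated
#' fraction with strong effects (|log2| 2.3-5.3), log-normal peptide base
#' intensities, multiplicative peptide-level noise and light channel-wise
#' missingness.
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param fraction_regulated Fraction of proteins with a planted effect
#'   (default 0.06).
#' @param effect_log2_min,effect_log2_max Magnitude range of planted log2
#'   effects (default 2.3-5.3).
#' @param background_mean,background_sd Background log2-ratio distribution
#'   (default Normal(-0.07, 0.8)).
#' @param peptide_noise_sd SD of peptide-level log2 noise (default 0.3).
#' @param peptides_per_protein_mean Poisson mean; peptides per protein are
#'   `1 + Poisson(mean)` (default 4).
#' @param base_intensity_median,base_intensity_gsd Log-normal base
#'   intensity median and geometric SD (defaults 1e6 and 4).
#' @param n_replicates Number of replicates (default 2).
#' @param replicate_shift_sd SD of the protein x replicate x channel log2
#'   shift (default 0.05).
#' @param missing_rate Channel-wise independent missingness (default 0.05).
#' @param incorporation Label incorporation used for peak-list simulation
#'   (default 1).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000,
                       fraction_regulated = 0.06,
                       effect_log2_min = 2.3,
                       effect_log2_max = 5.3,
                       background_mean = -0.07,
                       background_sd = 0.8,
                       peptide_noise_sd = 0.3,
                       peptides_per_protein_mean = 4,
                       base_intensity_median = 1e6,
                       base_intensity_gsd = 4,
                       n_replicates = 2,
                       replicate_shift_sd = 0.05,
                       missing_rate = 0.05,
                       incorporation = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  bad <- character()
  chk <- function(cond, field) if (!isTRUE(cond)) bad <<- c(bad, field)
  chk(n_proteins >= 1, "n_proteins")
  chk(fraction_regulated >= 0 && fraction_regulated <= 1, "fraction_regulated")
  chk(effect_log2_min > 0 && effect_log2_max >= effect_log2_min, "effect_log2_min/effect_log2_max")
  chk(background_sd >= 0, "background_sd")
  chk(peptide_noise_sd >= 0, "peptide_noise_sd")
  chk(peptides_per_protein_mean >= 0, "peptides_per_protein_mean")
  chk(base_intensity_median > 0 && base_intensity_gsd >= 1, "base_intensity_median/base_intensity_gsd")
  chk(n_replicates >= 1, "n_replicates")
  chk(replicate_shift_sd >= 0, "replicate_shift_sd")
  chk(missing_rate >= 0 && missing_rate <= 1, "missing_rate")
  chk(incorporation >= 0 && incorporation <= 1, "incorporation")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed")
  if (length(bad)) {
    abort(paste0("invalid simulation config field(s): ", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "sim_config")
}

random_sequences <- function(n, min_len = 6, max_len = 20) {
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  body <- matrix(sample(names(RESIDUE_MONO), n * (max_len - 1), replace = TRUE),
                 nrow = n)
  full <- do.call(paste0, as.data.frame(body, stringsAsFactors = FALSE))
  paste0(substr(full, 1, len - 1), sample(c("K", "R"), n, replace = TRUE))
}

#' Simulate three-channel peptide evidence with ground truth
#'
#' Draws per-protein true log2 M/L and H/L ratios from the background
#' distribution, overrides a `fraction_regulated` subset with strong signed
#' effects (applied to M/L only, H/L only, or both channels in the same or
#' opposite direction), and realizes each peptide observation as channel
#' intensities `base * 2^(true log2 + replicate shift + noise)` relative to
#' the light channel. Intensities are dropped channel-wise at
#' `missing_rate`; rows losing all three channels are removed. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `evidence` (the canonical evidence tibble, see
#'   [read_evidence()]) and `truth` (per protein: true log2 ratios,
#'   per-channel regulated flags and directions).
#' @export
simulate_evidence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "evidence"))
  n <- config$n_proteins
  proteins <- sprintf("P%05d", seq_len(n))

  true_ml <- rnorm(n, config$background_mean, config$background_sd)
  true_hl <- rnorm(n, config$background_mean, config$background_sd)
  reg_ml <- reg_hl <- rep(FALSE, n)

  n_reg <- round(config$fraction_regulated * n)
  if (n_reg > 0) {
    idx <- sample(n, n_reg)
    pattern <- sample(c("ml", "hl", "both_same", "both_opposite"), n_reg, replace = TRUE)
    dir <- sample(c(-1, 1), n_reg, replace = TRUE)
    mag_ml <- runif(n_reg, config$effect_log2_min, config$effect_log2_max)
    mag_hl <- runif(n_reg, config$effect_log2_min, config$effect_log2_max)
    in_ml <- pattern %in% c("ml", "both_same", "both_opposite")
    in_hl <- pattern %in% c("hl", "both_same", "both_opposite")
    hl_dir <- ifelse(pattern == "both_opposite", -dir, dir)
    true_ml[idx[in_ml]] <- (dir * mag_ml)[in_ml]
    true_hl[idx[in_hl]] <- (hl_dir * mag_hl)[in_hl]
    reg_ml[idx[in_ml]] <- TRUE
    reg_hl[idx[in_hl]] <- TRUE
  }

  truth <- tibble::tibble(
    protein = proteins,
    true_log2_ml = true_ml, true_log2_hl = true_hl,
    regulated_ml = reg_ml, regulated_hl = reg_hl,
    direction_ml = ifelse(reg_ml, ifelse(true_ml > 0, "up", "down"), "none"),
    direction_hl = ifelse(reg_hl, ifelse(true_hl > 0, "up", "down"), "none"),
    regulated = reg_ml | reg_hl
  )

  n_pep <- 1 + rpois(n, config$peptides_per_protein_mean)
  pep_protein <- rep(seq_len(n), n_pep)
  total_pep <- length(pep_protein)
  sequences <- random_sequences(total_pep)
  charges <- sample(2:3, total_pep, replace = TRUE)

  reps <- seq_len(config$n_replicates)
  ev <- purrr::map_dfr(reps, function(r) {
    base <- rlnorm(total_pep, log(config$base_intensity_median),
                   log(config$base_intensity_gsd))
    shift_ml <- rnorm(n, 0, config$replicate_shift_sd)[pep_protein]
    shift_hl <- rnorm(n, 0, config$replicate_shift_sd)[pep_protein]
    noise_ml <- rnorm(total_pep, 0, config$peptide_noise_sd)
    noise_hl <- rnorm(total_pep, 0, config$peptide_noise_sd)
    l <- base
    m <- base * 2^(true_ml[pep_protein] + shift_ml + noise_ml)
    h <- base * 2^(true_hl[pep_protein] + shift_hl + noise_hl)
    if (config$missing_rate > 0) {
      l[runif(total_pep) < config$missing_rate] <- NA_real_
      m[runif(total_pep) < config$missing_rate] <- NA_real_
      h[runif(total_pep) < config$missing_rate] <- NA_real_
    }
    tibble::tibble(
      sequence = sequences,
      protein = proteins[pep_protein],
      charge = charges,
      intensity_l = l, intensity_m = m, intensity_h = h,
      replicate = paste0("rep", r)
    )
  })
  ev <- dplyr::filter(ev, !(is.na(.data$intensity_l) & is.na(.data$intensity_m) &
                              is.na(.data$intensity_h)))
  list(evidence = ev, truth = truth)
}

#' Simulate a centroided peak list for one peptide
#'
#' Plants the channel peaks of a peptide at exact label spacings for its
#' charge, with residual light signal `(1 - incorporation)` of each
#' labelled channel's intensity, optional Arg-to-Pro conversion satellites
#' at `conversion_fraction` of the channel peak, and uniform random noise
#' peaks.
#'
#' @param spec One-row tibble from [peptide_spec()].
#' @param channels Channels whose peaks are planted. The default plants all
#'   three (a 1:1:1 mix); use `c("medium", "heavy")` for an
#'   incorporation-efficiency scenario where any light signal comes only
#'   from incomplete labelling.
#' @param incorporation Label incorporation fraction in labelled channels.
#' @param conversion_fraction Satellite intensity as a fraction of the
#'   channel peak (0 = no conversion).
#' @param n_noise_peaks Number of uniform noise peaks added.
#' @param base_intensity Intensity of a fully incorporated channel peak.
#' @param seed Integer seed.
#' @param scheme Label scheme, see [silac_scheme()].
#' @return List with `peaks` (tibble `mz`, `intensity`, sorted) and `truth`
#'   (planted peaks: `channel`, `mz`, `intensity`, plus satellite rows).
#' @export
simulate_peaklist <- function(spec, channels = c("light", "medium", "heavy"),
                              incorporation = 1, conversion_fraction = 0,
                              n_noise_peaks = 0, base_intensity = 1e6,
                              seed = 1L, scheme = silac_scheme()) {
  stopifnot(nrow(spec) == 1, incorporation >= 0, incorporation <= 1)
  channels <- match.arg(channels, several.ok = TRUE)
  set.seed(derive_seed(seed, "peaklist"))

  light_mz <- peptide_mz(spec, "light", scheme)
  planted <- tibble::tibble(channel = character(), mz = numeric(), intensity = numeric())
  light_int <- 0
  for (ch in channels) {
    if (ch == "light") {
      light_int <- light_int + base_intensity
    } else {
      ch_int <- base_intensity * incorporation
      light_int <- light_int + base_intensity * (1 - incorporation)
      if (ch_int > 0) {
        planted <- dplyr::add_row(planted, channel = ch,
                                  mz = peptide_mz(spec, ch, scheme), intensity = ch_int)
        if (conversion_fraction > 0 && spec$n_pro > 0) {
          planted <- dplyr::add_row(
            planted, channel = paste0(ch, "_pro_satellite"),
            mz = peptide_mz(spec, ch, scheme) + scheme_row(ch, scheme)$pro_delta / spec$charge,
            intensity = ch_int * conversion_fraction
          )
        }
      }
    }
  }
  if (light_int > 0) {
    planted <- dplyr::add_row(planted, channel = "light", mz = light_mz,
                              intensity = light_int, .before = 1)
  }

  peaks <- planted[, c("mz", "intensity")]
  if (n_noise_peaks > 0) {
    lo <- min(planted$mz, light_mz) - 50
    hi <- max(planted$mz, light_mz) + 50
    peaks <- dplyr::bind_rows(peaks, tibble::tibble(
      mz = runif(n_noise_peaks, lo, hi),
      intensity = runif(n_noise_peaks, 0.01, 0.3) * base_intensity
    ))
  }
  peaks <- dplyr::arrange(peaks, .data$mz)
  list(peaks = peaks, truth = planted)
}

#' Simulate a flat annotation table with optional planted enrichment
#'
#' Assigns proteins to synthetic annotation terms. Background terms sample
#' members uniformly from the background; planted terms sample with weight
#' `1 + enrichment_strength` on regulated proteins, so high strength makes
#' them strongly over-represented in the regulated set.
#'
#' @param truth Ground-truth tibble from [simulate_evidence()].
#' @param n_terms Total number of terms (default 10).
#' @param planted_terms Number of terms with preferential coverage
#'   (default 0).
#' @param enrichment_strength Extra sampling weight on regulated proteins
#'   for planted terms (0 = uniform).
#' @param term_size_range Inclusive range of term sizes (default 3-10,
#'   emulating small, specific annotation categories).
#' @param seed Integer seed.
#' @return List with `annotations` (tibble `accession`, `term_id`,
#'   `term_label`, `namespace`) and `planted` (ids of planted terms).
#' @export
simulate_annotations <- function(truth, n_terms = 10, planted_terms = 0,
                                 enrichment_strength = 0,
                                 term_size_range = c(3, 10), seed = 1L) {
  stopifnot(planted_terms <= n_terms, enrichment_strength >= 0)
  set.seed(derive_seed(seed, "annotations"))
  background <- truth$protein
  weights <- 1 + enrichment_strength * as.numeric(truth$regulated)
  ids <- sprintf("T%04d", seq_len(n_terms))
  sizes <- seq(term_size_range[1], term_size_range[2])
  ann <- purrr::map_dfr(seq_len(n_terms), function(t) {
    size <- if (length(sizes) == 1) sizes else sample(sizes, 1)
    w <- if (t <= planted_terms) weights else rep(1, length(background))
    tibble::tibble(
      accession = sample(background, size, prob = w),
      term_id = ids[t],
      term_label = sprintf("synthetic term %d", t),
      namespace = "synthetic"
    )
  })
  list(annotations = ann, planted = ids[seq_len(planted_terms)])
}
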