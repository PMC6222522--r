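#' Simulation configuration
#'
#' Settings of the synthetic LC-MS feature generator. Defaults emulate the
#' study conditions the pipeline targets: triplicate negative-mode
#' injections of two contrasted samples, 5 ppm mass error (a realistic
#' Q-TOF accuracy, and a quarter of the 20 ppm matching tolerance),
#' log-normal abundances, and a linear retention model in which RT grows
#' with degree of polymerization, extra B-ring hydroxylation and
#' galloylation -- the qualitative HILIC trends. The RT coefficients are a
#' test harness loosely placed near observed mean retention times, not a
#' retention-prediction claim.
#'
#' @param seed Integer seed; identical (seed, config) gives identical
#'   output.
#' @param compounds What to plant: `NULL` (the default) plants the 21
#'   published wine proanthocyanidin compositions from [published_compounds()]
#'   — the compound universe the pipeline is meant to emulate; the string
#'   `"sample"` draws `n_compounds` entries at random from the whole
#'   database (note that formula near-degeneracies above ~DP 5 then make
#'   some wrong-formula assignments unavoidable at realistic mass error);
#'   or a character vector of composition names.
#' @param n_compounds Number of database entries drawn when
#'   `compounds = "sample"`.
#' @param ppm_sigma Gaussian m/z error s.d. in ppm.
#' @param rt_intercept RT (min) of a DP-2 polymer with no extras.
#' @param rt_dp_step RT increment per DP unit (min).
#' @param rt_oxygen_step RT increment per extra B-ring oxygen (min).
#' @param rt_gallate_step RT increment per gallate ester (min).
#' @param rt_sigma RT noise s.d. (min).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance
#'   parameters.
#' @param sample_multipliers Named numeric vector of per-sample abundance
#'   multipliers; the names are the sample ids.
#' @param replicates Injections per sample (>= 1).
#' @param n_noise Number of random noise features per sample x replicate.
#' @param mz_range Noise m/z range (the acquisition window).
#' @param doubly_charged_fraction Probability that a planted compound of
#'   `dp >= doubly_charged_min_dp` is observed as its [M-2H]2- ion.
#' @param doubly_charged_min_dp Minimum DP eligible for z = 2.
#' @param msms_keep_fraction Fraction of the fragment set kept in a
#'   simulated MS/MS spectrum.
#' @param msms_n_noise Noise peaks added to a simulated MS/MS spectrum.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, compounds = NULL, n_compounds = 100,
                       ppm_sigma = 5,
                       rt_intercept = 5.1, rt_dp_step = 2.2,
                       rt_oxygen_step = 0.9, rt_gallate_step = 0.25,
                       rt_sigma = 0.05,
                       abundance_meanlog = log(5e4), abundance_sdlog = 1,
                       sample_multipliers = c(wine_a = 1, wine_b = 3),
                       replicates = 3,
                       n_noise = 50, mz_range = c(100, 3200),
                       doubly_charged_fraction = 0.5,
                       doubly_charged_min_dp = 4,
                       msms_keep_fraction = 0.8, msms_n_noise = 5) {
  stopifnot(ppm_sigma >= 0, rt_sigma >= 0, replicates >= 1, n_noise >= 0,
            length(mz_range) == 2, mz_range[1] < mz_range[2],
            doubly_charged_fraction >= 0, doubly_charged_fraction <= 1,
            msms_keep_fraction > 0, msms_keep_fraction <= 1)
  if (is.null(names(sample_multipliers))) {
    names(sample_multipliers) <- paste0("sample_",
                                        seq_along(sample_multipliers))
  }
  structure(as.list(environment()), class = "sim_config")
}

# deterministic RT model: DP, extra oxygens (gallocatechin-type units) and
# gallates each push retention later
.rt_model <- function(db_rows, config) {
  x <- db_rows$n_galcat + db_rows$n_galcatgal
  g <- db_rows$n_catgal + db_rows$n_galcatgal
  config$rt_intercept + config$rt_dp_step * (db_rows$dp - 2) +
    config$rt_oxygen_step * x + config$rt_gallate_step * g
}

# sorted m/z values of every allowed ion interpretation of the database,
# used to keep noise features away from real signals
.db_ion_mz <- function(db) {
  sort(c(mz_from_mass(db$neutral_mass, "deprotonated", 1),
         mz_from_mass(db$neutral_mass, "deprotonated", 2),
         mz_from_mass(db$neutral_mass, "formate", 1)))
}

#' Simulate a deisotoped negative-mode feature table
#'
#' Plants the configured compounds as [M-H]- (or [M-2H]2- for larger
#' polymers) features across samples and replicates: observed m/z is the
#' true ion m/z times `(1 + e)` with `e ~ N(0, ppm_sigma * 1e-6)`, RT comes
#' from the linear retention model plus noise, abundance is log-normal
#' scaled by the per-sample multiplier. Uniform-random noise features are
#' added, rejection-sampled to lie at least 30 ppm from every database ion
#' so false-positive behaviour is well defined. Adducts are emitted as
#' `"unknown"` so matching has to infer them.
#'
#' @param db A `pcd_db` tibble.
#' @param config A [sim_config()].
#' @return A `pcd_simulation` object: list with `features` (the matching
#'   input dialect), `truth` (per feature: `true_formula`,
#'   `true_composition`, `true_adduct`, `true_charge`, `is_noise`) and the
#'   `config`.
#' @export
simulate_features <- function(db, config = sim_config()) {
  set.seed(config$seed)
  compounds <- config$compounds
  if (is.null(compounds)) compounds <- published_compounds()$polymer
  if (identical(compounds, "sample")) {
    planted <- db[sample.int(nrow(db), min(config$n_compounds, nrow(db))), ]
  } else {
    miss <- setdiff(compounds, db$name)
    if (length(miss) > 0) {
      stop(sprintf("compound `%s` is not in the database", miss[1]),
           call. = FALSE)
    }
    planted <- db[match(compounds, db$name), ]
  }

  planted$charge <- ifelse(
    planted$dp >= config$doubly_charged_min_dp &
      stats::runif(nrow(planted)) < config$doubly_charged_fraction, 2L, 1L)
  planted$true_mz <- (planted$neutral_mass -
                        planted$charge * .proton_mass) / planted$charge
  planted$rt_center <- .rt_model(planted, config)

  samples <- names(config$sample_multipliers)
  grid <- tidyr::crossing(
    compound_idx = seq_len(nrow(planted)),
    sample_id = samples,
    replicate = paste0("r", seq_len(config$replicates))
  )
  p <- planted[grid$compound_idx, ]
  n <- nrow(grid)
  features <- tibble::tibble(
    sample_id = grid$sample_id,
    replicate = grid$replicate,
    rt = p$rt_center + stats::rnorm(n, 0, config$rt_sigma),
    mz = p$true_mz * (1 + stats::rnorm(n, 0, config$ppm_sigma * 1e-6)),
    charge = p$charge,
    adduct = "unknown",
    abundance = stats::rlnorm(n, config$abundance_meanlog,
                              config$abundance_sdlog) *
      unname(config$sample_multipliers[grid$sample_id])
  )
  truth <- tibble::tibble(
    true_formula = p$formula,
    true_composition = p$name,
    true_adduct = "deprotonated",
    true_charge = p$charge,
    is_noise = FALSE
  )

  n_noise_total <- config$n_noise * length(samples) * config$replicates
  if (n_noise_total > 0) {
    ions <- .db_ion_mz(db)
    draw_clean <- function(k) {
      out <- numeric(0)
      while (length(out) < k) {
        cand <- stats::runif(k - length(out), config$mz_range[1],
                             config$mz_range[2])
        i <- findInterval(cand, ions)
        near <- pmin(
          abs(cand - ions[pmax(i, 1)]),
          abs(ions[pmin(i + 1, length(ions))] - cand)
        ) / cand * 1e6
        out <- c(out, cand[near > 30])
      }
      out
    }
    ngrid <- tidyr::crossing(
      sample_id = samples,
      replicate = paste0("r", seq_len(config$replicates)),
      k = seq_len(config$n_noise)
    )
    noise <- tibble::tibble(
      sample_id = ngrid$sample_id,
      replicate = ngrid$replicate,
      rt = stats::runif(n_noise_total, 4.5, 16),
      mz = draw_clean(n_noise_total),
      charge = sample(c(1L, 2L), n_noise_total, replace = TRUE),
      adduct = "unknown",
      abundance = stats::rlnorm(n_noise_total, config$abundance_meanlog,
                                config$abundance_sdlog)
    )
    features <- dplyr::bind_rows(features, noise)
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      true_formula = rep(NA_character_, n_noise_total),
      true_composition = NA_character_,
      true_adduct = NA_character_,
      true_charge = NA_integer_,
      is_noise = TRUE
    ))
  }

  features <- dplyr::bind_cols(
    tibble::tibble(feature_id = seq_len(nrow(features))), features)
  truth <- dplyr::bind_cols(
    tibble::tibble(feature_id = seq_len(nrow(truth))), truth)
  structure(list(features = features, truth = truth, config = config),
            class = "pcd_simulation")
}

#' @export
tidy.pcd_simulation <- function(x, ...) {
  dplyr::left_join(x$features, x$truth, by = "feature_id")
}

#' @export
print.pcd_simulation <- function(x, ...) {
  cat(sprintf("<pcd_simulation> %d features (%d planted, %d noise), seed %d\n",
              nrow(x$features), sum(!x$truth$is_noise),
              sum(x$truth$is_noise), x$config$seed))
  invisible(x)
}

#' Simulate an MS/MS spectrum of a composition
#'
#' Takes a random subsample of the theoretical fragment set, jitters each
#' m/z by the configured ppm error, assigns log-normal intensities and adds
#' uniform noise peaks. The ground truth maps each signal peak to its
#' fragment.
#'
#' @param composition Composition name or count vector.
#' @param config A [sim_config()]; uses `seed`, `ppm_sigma`,
#'   `msms_keep_fraction`, `msms_n_noise`.
#' @param ... Passed to [generate_fragments()].
#' @return List with `spectrum` (tibble `mz`, `intensity`) and `truth`
#'   (fragment rows with the emitted m/z).
#' @export
simulate_msms <- function(composition, config = sim_config(), ...) {
  set.seed(config$seed)
  frags <- generate_fragments(composition, ...)
  keep <- sort(sample.int(nrow(frags),
                          max(1, round(config$msms_keep_fraction *
                                         nrow(frags)))))
  kept <- frags[keep, ]
  mz <- kept$mz * (1 + stats::rnorm(nrow(kept), 0, config$ppm_sigma * 1e-6))
  intensity <- stats::rlnorm(nrow(kept), log(1e4), 1)
  spectrum <- tibble::tibble(mz = mz, intensity = intensity)
  truth <- dplyr::bind_cols(kept, tibble::tibble(emitted_mz = mz))
  if (config$msms_n_noise > 0) {
    noise_mz <- stats::runif(config$msms_n_noise, 100,
                             max(frags$mz) * 1.05)
    spectrum <- dplyr::bind_rows(spectrum, tibble::tibble(
      mz = noise_mz,
      intensity = stats::rlnorm(config$msms_n_noise, log(500), 0.5)))
  }
  spectrum <- spectrum[order(spectrum$mz), ]
  list(spectrum = spectrum, truth = truth)
}

#' Packaged table of identified wine proanthocyanidins
#'
#' The published identification table shipped with the package: 21
#' formula-level rows (89 retention-time entries in total) with per-row
#' isomer retention times, canonical composition, mean experimental
#' neutral mass, mean unsigned ppm error, and whether the species was
#' observed doubly charged. The printed heptamer formula contains a
#' typesetting artifact; the fixture stores the arithmetically consistent
#' C105H86O42.
#'
#' @return A tibble with columns `rt_list` (list of numeric RTs),
#'   `mean_rt`, `formula`, `polymer`, `mean_experimental_mass`,
#'   `mean_ppm_error`, `doubly_charged`.
#' @export
published_compounds <- function() {
  path <- system.file("extdata", "identified_compounds.csv",
                      package = "pcdkit", mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    rt_list = lapply(strsplit(x$rt_list, ";", fixed = TRUE), as.numeric),
    mean_rt = x$mean_rt,
    formula = x$formula,
    polymer = x$polymer,
    mean_experimental_mass = x$mean_experimental_mass,
    mean_ppm_error = x$mean_ppm_error,
    doubly_charged = x$doubly_charged
  )
}

#' Replay the packaged identification table as exact-mass features
#'
#' One feature per retention-time entry, with m/z computed from the row's
#' mean experimental neutral mass under the row's observed charge state
#' (deprotonated), for end-to-end filter/match/group tests without
#' instrument data.
#'
#' @param fixture Output of [published_compounds()].
#' @param sample_id,replicate Labels stamped on every feature.
#' @param abundance Constant abundance given to every feature.
#' @return A feature tibble in the matching input dialect.
#' @export
fixture_features <- function(fixture = published_compounds(),
                             sample_id = "wine", replicate = "r1",
                             abundance = 10000) {
  rows <- purrr::map_dfr(seq_len(nrow(fixture)), function(i) {
    z <- if (fixture$doubly_charged[i]) 2L else 1L
    tibble::tibble(
      sample_id = sample_id,
      replicate = replicate,
      rt = fixture$rt_list[[i]],
      mz = (fixture$mean_experimental_mass[i] - z * .proton_mass) / z,
      charge = z,
      adduct = "deprotonated",
      abundance = abundance
    )
  })
  dplyr::bind_cols(tibble::tibble(feature_id = seq_len(nrow(rows))), rows)
}

#' Write features (and ground truth) in the package CSV dialects
#'
#' @param features Feature tibble.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}
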