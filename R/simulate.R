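#' Configuration for the paired Ct-cohort simulator
#'
#' Defaults emulate the structure of a paired prostate qPCR-array study:
#' 19 analyzable cases each contributing one malignant and one adjacent
#' normal sample, 667 unique miRNAs per array, a small set of truly
#' differential miRNAs with fixed Ct-shift effects, a between-case random
#' effect shared by both members of a pair, per-array additive technical
#' offsets (the nuisance quantile normalization removes), Gaussian well
#' noise, missing wells, and a 40-cycle detection ceiling.
#'
#' Because Ct falls as template abundance rises, increased expression in
#' malignant tissue is encoded as a Ct *decrease*; every direction call
#' downstream relies on this one convention.
#'
#' @param n_cases number of cases; each yields a normal/malignant pair.
#' @param n_features number of miRNAs on the array.
#' @param n_de number of truly differentially expressed miRNAs.
#' @param effect_ct Ct-shift magnitude (cycles) of each DE miRNA.
#' @param effect_sign_fraction_up fraction of DE miRNAs up-regulated in
#'   malignant tissue (Ct decrease).
#' @param baseline_ct_range interval from which per-feature baseline mean
#'   Ct is drawn uniformly.
#' @param case_sd SD (cycles) of the between-case random effect.
#' @param noise_sd residual well-level SD (cycles).
#' @param array_offset_sd SD (cycles) of the per-array additive offset.
#' @param missing_rate probability a well is missing completely at random.
#' @param ct_max detection ceiling; wells beyond it are censored to
#'   missing, mimicking "Undetermined" reactions.
#' @param gleason_profile optional [gleason_profile()] giving malignant
#'   samples score-dependent shifts on a second feature set.
#' @param seed RNG seed; equal configs with equal seeds reproduce
#'   bit-identical datasets.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 19, n_features = 667, n_de = 9,
                              effect_ct = 2, effect_sign_fraction_up = 0.5,
                              baseline_ct_range = c(20, 35),
                              case_sd = 1, noise_sd = 0.5,
                              array_offset_sd = 1, missing_rate = 0.05,
                              ct_max = 40, gleason_profile = NULL,
                              seed = NULL) {
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
        x < min) {
      stop("invalid '", nm, "': must be an integer >= ", min)
    }
  }
  chk_sd <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      stop("invalid '", nm, "': must be a non-negative number")
    }
  }
  chk_count(n_cases, "n_cases", 2)
  chk_count(n_features, "n_features", 1)
  chk_count(n_de, "n_de", 0)
  if (n_de > n_features) stop("invalid 'n_de': must not exceed n_features")
  chk_sd(effect_ct, "effect_ct")
  if (!is.numeric(effect_sign_fraction_up) ||
      effect_sign_fraction_up < 0 || effect_sign_fraction_up > 1) {
    stop("invalid 'effect_sign_fraction_up': must lie in [0, 1]")
  }
  if (!is.numeric(baseline_ct_range) || length(baseline_ct_range) != 2L ||
      baseline_ct_range[1] <= 0 ||
      baseline_ct_range[2] < baseline_ct_range[1]) {
    stop("invalid 'baseline_ct_range': need 0 < low <= high")
  }
  chk_sd(case_sd, "case_sd")
  chk_sd(noise_sd, "noise_sd")
  chk_sd(array_offset_sd, "array_offset_sd")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("invalid 'missing_rate': must lie in [0, 1)")
  }
  if (!is.numeric(ct_max) || ct_max <= 0) {
    stop("invalid 'ct_max': must be positive")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_features = as.integer(n_features),
                 n_de = as.integer(n_de), effect_ct = effect_ct,
                 effect_sign_fraction_up = effect_sign_fraction_up,
                 baseline_ct_range = baseline_ct_range, case_sd = case_sd,
                 noise_sd = noise_sd, array_offset_sd = array_offset_sd,
                 missing_rate = missing_rate, ct_max = ct_max,
                 gleason_profile = gleason_profile, seed = seed),
            class = "simulation_config")
}

#' Gleason subgroup profile for the simulator
#'
#' Assigns each malignant sample a Gleason score and plants
#' score-dependent Ct shifts on a dedicated feature subset (disjoint from
#' the normal-vs-malignant DE set), creating subgroup structure among the
#' malignant samples only. Per (feature, score) shifts are drawn uniformly
#' from `[-effect_ct, effect_ct]`, so distinct scores get distinct
#' multivariate centroids.
#'
#' @param scores either a vector of score levels recycled over cases in
#'   order, or a full per-case assignment of length `n_cases`. At least 2
#'   distinct scores are required.
#' @param n_features number of subgroup-informative miRNAs.
#' @param effect_ct half-width (cycles) of the per-score shift range.
#' @return object of class `gleason_profile`.
#' @export
gleason_profile <- function(scores = c(6, 7, 9, 10), n_features = 16,
                            effect_ct = 2) {
  if (length(unique(scores)) < 2L) {
    stop("gleason_profile must assign at least 2 distinct scores")
  }
  if (any(scores < 6 | scores > 10)) stop("Gleason scores must lie in [6, 10]")
  if (!is.numeric(n_features) || n_features < 1) {
    stop("invalid 'n_features' in gleason_profile")
  }
  if (!is.numeric(effect_ct) || effect_ct < 0) {
    stop("invalid 'effect_ct' in gleason_profile")
  }
  structure(list(scores = scores, n_features = as.integer(n_features),
                 effect_ct = effect_ct),
            class = "gleason_profile")
}

#' Generate a paired Ct dataset with planted effects
#'
#' Model per well:
#' `Ct = baseline(feature) + case_effect(case) + array_offset(sample) +
#' DE shift (malignant wells of DE features) + Gleason shift (optional) +
#' noise`, censored to missing above `ct_max`, then masked missing
#' completely at random at `missing_rate`.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_dataset`: list with
#'   \describe{
#'     \item{ct}{Ct matrix, `n_features` x `2 * n_cases`;}
#'     \item{annotation}{sample annotation with paired case ids;}
#'     \item{truth_de}{data.frame of planted DE features: `feature_id`,
#'       `direction` (expression in malignant), `ct_shift` (signed, Ct
#'       scale);}
#'     \item{truth_subgroups}{named malignant-sample -> Gleason score
#'       vector, when a `gleason_profile` is present;}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
generate_paired_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a 'simulation_config'")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  nc <- config$n_cases
  nf <- config$n_features
  ns <- 2L * nc

  features <- sprintf("miR-%04d", seq_len(nf))
  cases <- sprintf("case%02d", seq_len(nc))
  sample_id <- as.vector(rbind(paste0("s", sprintf("%02d", seq_len(nc)), "N"),
                               paste0("s", sprintf("%02d", seq_len(nc)), "M")))
  case_of <- rep(seq_len(nc), each = 2L)
  tissue <- rep(c("normal", "malignant"), times = nc)
  malignant <- tissue == "malignant"

  # planted differential features: "+" = up in malignant = Ct decrease
  de_idx <- if (config$n_de > 0L) sample.int(nf, config$n_de) else integer(0)
  n_up <- round(config$effect_sign_fraction_up * config$n_de)
  de_dir <- rep(c("+", "-"), times = c(n_up, config$n_de - n_up))
  shift <- numeric(nf)
  shift[de_idx] <- ifelse(de_dir == "+", -config$effect_ct, config$effect_ct)

  baseline <- stats::runif(nf, config$baseline_ct_range[1],
                           config$baseline_ct_range[2])
  case_eff <- stats::rnorm(nc, 0, config$case_sd)
  offset <- stats::rnorm(ns, 0, config$array_offset_sd)

  ct <- matrix(baseline, nf, ns) +
    matrix(case_eff[case_of], nf, ns, byrow = TRUE) +
    matrix(offset, nf, ns, byrow = TRUE)
  ct[, malignant] <- ct[, malignant] + shift

  gleason_score <- rep(NA_real_, ns)
  truth_subgroups <- NULL
  gp <- config$gleason_profile
  if (!is.null(gp)) {
    if (!inherits(gp, "gleason_profile")) {
      stop("gleason_profile must be built with gleason_profile()")
    }
    score_of_case <- if (length(gp$scores) == nc) gp$scores
                     else rep(gp$scores, length.out = nc)
    if (length(unique(score_of_case)) < 2L) {
      stop("gleason_profile must assign at least 2 distinct scores")
    }
    avail <- setdiff(seq_len(nf), de_idx)
    if (length(avail) < gp$n_features) {
      stop("not enough non-DE features for the gleason_profile subset")
    }
    sub_idx <- sample(avail, gp$n_features)
    lev <- sort(unique(score_of_case))
    G <- matrix(stats::runif(gp$n_features * length(lev),
                             -gp$effect_ct, gp$effect_ct),
                nrow = gp$n_features,
                dimnames = list(NULL, as.character(lev)))
    for (i in seq_len(nc)) {
      col <- 2L * i            # malignant member of case i
      ct[sub_idx, col] <- ct[sub_idx, col] +
        G[, as.character(score_of_case[i])]
    }
    gleason_score[malignant] <- score_of_case[case_of[malignant]]
    truth_subgroups <- stats::setNames(score_of_case,
                                       sample_id[malignant])
    attr(truth_subgroups, "feature_ids") <- features[sub_idx]
  }

  ct <- ct + matrix(stats::rnorm(nf * ns, 0, config$noise_sd), nf, ns)
  ct[ct > config$ct_max] <- NA_real_          # ceiling-censored wells
  if (config$missing_rate > 0) {
    ct[matrix(stats::runif(nf * ns) < config$missing_rate, nf, ns)] <- NA_real_
  }
  dimnames(ct) <- list(features, sample_id)

  annotation <- data.frame(
    sample_id = sample_id,
    case_id = cases[case_of],
    tissue_class = tissue,
    gleason_score = gleason_score,
    tumor_pct = NA_real_,
    who_grade = NA_real_,
    stringsAsFactors = FALSE
  )

  truth_de <- data.frame(
    feature_id = features[de_idx],
    direction = de_dir,
    ct_shift = shift[de_idx],
    stringsAsFactors = FALSE
  )

  structure(list(ct = ct, annotation = annotation, truth_de = truth_de,
                 truth_subgroups = truth_subgroups, config = config),
            class = "synthetic_dataset")
}

#' Generate a null paired dataset (no differential features)
#'
#' As [generate_paired_dataset()] with `n_de` forced to zero; the truth
#' set is empty. Used for type-I-error and permutation-control checks.
#'
#' @inheritParams generate_paired_dataset
#' @return a `synthetic_dataset` with empty `truth_de`.
#' @export
generate_null_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a 'simulation_config'")
  }
  config$n_de <- 0L
  generate_paired_dataset(config)
}

#' Generate a paired dataset with Gleason-linked subgroups
#'
#' Requires a `gleason_profile` in the configuration; a designated
#' feature subset carries score-dependent Ct means among the malignant
#' samples and `truth_subgroups` is populated.
#'
#' @inheritParams generate_paired_dataset
#' @return a `synthetic_dataset` with `truth_subgroups` set.
#' @export
generate_gleason_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a 'simulation_config'")
  }
  if (is.null(config$gleason_profile)) {
    stop("configuration error: generate_gleason_dataset requires a gleason_profile")
  }
  generate_paired_dataset(config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic paired Ct dataset:", nrow(x$ct), "miRNAs x",
      ncol(x$ct), "samples (", x$config$n_cases, "pairs )\n")
  cat("  planted DE features:", nrow(x$truth_de), "\n")
  if (!is.null(x$truth_subgroups)) {
    cat("  Gleason subgroups:",
        paste(sort(unique(x$truth_subgroups)), collapse = "/"), "\n")
  }
  cat("  missing wells:", sum(is.na(x$ct)), "\n")
  invisible(x)
}

#' Write a synthetic dataset to delimited text
#'
#' Emits `ct.csv`, `annotation.csv` and `truth_de.csv` (plus
#' `truth_subgroups.csv` when present) into `dir`, in the formats read by
#' [read_ct_table()] and [read_sample_annotation()].
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_table(ds$ct, file.path(dir, "ct.csv"))
  write_sample_annotation(ds$annotation, file.path(dir, "annotation.csv"))
  utils::write.table(ds$truth_de, file.path(dir, "truth_de.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(ds$truth_subgroups)) {
    utils::write.table(
      data.frame(sample_id = names(ds$truth_subgroups),
                 gleason_score = as.vector(ds$truth_subgroups)),
      file.path(dir, "truth_subgroups.csv"),
      sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
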