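#' Configuration for a synthetic endometrial-receptivity cohort
#'
#' Defines the statistical structure of a simulated hormone-replacement (HRT)
#' cycle cohort: how many patients, how many genes, which fraction of
#' patients have a receptive endometrium at the standard transfer time
#' (P+5 = 120 h after the first progesterone administration), how delayed
#' windows of implantation (WOI) are distributed, and how pregnancy
#' probability decays with transfer--WOI misalignment.
#'
#' All times are real-valued hours after the first progesterone
#' administration; "P+n" denotes `24 * n` hours.
#'
#' @param n_patients Number of patients.
#' @param n_genes Total genes in the expression matrix (markers + background).
#' @param n_markers Number of genes whose expression tracks time relative to
#'   the patient's WOI center. Default 175, the size of a typical
#'   receptivity marker panel.
#' @param receptive_fraction Probability that a patient's WOI center
#'   coincides with the reference time (zero displacement). Default 0.391.
#' @param delay_min,delay_max Bounds (hours) of the uniform distribution of
#'   WOI delays among displaced patients. Default 13--96 h: strictly beyond
#'   the receptive half-width and within the labeling grid.
#' @param reference_woi_hours Reference WOI center, hours after first
#'   progesterone administration. Default 120 (P+5, standard blastocyst
#'   transfer timing).
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to
#'   log2-scale expression.
#' @param scale `"log"` for log2-scale Gaussian abundances (default) or
#'   `"counts"` for negative-binomial counts with the same log2 mean
#'   structure.
#' @param nb_size Negative-binomial size (inverse dispersion) used when
#'   `scale = "counts"`.
#' @param signed_displacement If `TRUE`, displaced patients are advanced or
#'   delayed with equal probability; by default displacement is delay-only,
#'   matching cohorts in which every observed displacement is a delay.
#' @param p_max Peak clinical-pregnancy probability at a perfectly aligned
#'   transfer. Default 0.55.
#' @param p_bio_given_hcg Fraction of hCG-positive cycles that end as
#'   biochemical pregnancies. Default 0.15.
#' @param decay_scale_hours Gaussian decay scale (hours) of
#'   clinical-pregnancy probability in the transfer--WOI misalignment.
#'   Default 36 h; see the package vignette for the calibration rationale.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [sample_biopsies()],
#'   [simulate_transfer_outcome()]
#' @export
cohort_config <- function(n_patients,
                          n_genes = 2000L,
                          n_markers = 175L,
                          receptive_fraction = 0.391,
                          delay_min = 13,
                          delay_max = 96,
                          reference_woi_hours = 120,
                          noise_sd = 0.25,
                          scale = c("log", "counts"),
                          nb_size = 10,
                          signed_displacement = FALSE,
                          p_max = 0.55,
                          p_bio_given_hcg = 0.15,
                          decay_scale_hours = 36,
                          seed = 1L) {
  scale <- match.arg(scale)
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("n_patients", "n_genes", "n_markers", "receptive_fraction",
               "delay_min", "delay_max", "reference_woi_hours", "noise_sd",
               "nb_size", "p_max", "p_bio_given_hcg", "seed")) {
    if (!num_ok(get(nm))) {
      stop("cohort_config: '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (!num_ok(decay_scale_hours) && !identical(decay_scale_hours, Inf)) {
    stop("cohort_config: 'decay_scale_hours' must be a single positive number (Inf allowed)",
         call. = FALSE)
  }
  n_patients <- as.integer(n_patients)
  n_genes <- as.integer(n_genes)
  n_markers <- as.integer(n_markers)
  if (n_patients < 1L) stop("need at least one patient", call. = FALSE)
  if (n_markers > n_genes) {
    stop("n_markers must not exceed n_genes", call. = FALSE)
  }
  if (receptive_fraction < 0 || receptive_fraction > 1) {
    stop("receptive_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (delay_min <= 0 || delay_max < delay_min) {
    stop("delay distribution must have positive support with delay_min <= delay_max",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p_max < 0 || p_max > 1) stop("p_max must lie in [0, 1]", call. = FALSE)
  if (p_bio_given_hcg < 0 || p_bio_given_hcg >= 1) {
    stop("p_bio_given_hcg must lie in [0, 1)", call. = FALSE)
  }
  if (decay_scale_hours <= 0) {
    stop("decay_scale_hours must be positive", call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, n_genes = n_genes, n_markers = n_markers,
         receptive_fraction = receptive_fraction,
         delay_min = delay_min, delay_max = delay_max,
         reference_woi_hours = reference_woi_hours,
         noise_sd = noise_sd, scale = scale, nb_size = nb_size,
         signed_displacement = isTRUE(signed_displacement),
         p_max = p_max, p_bio_given_hcg = p_bio_given_hcg,
         decay_scale_hours = decay_scale_hours,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Generate a synthetic cohort with known WOI displacements
#'
#' Draws per-patient ground truth (receptive vs. displaced WOI) and
#' per-gene trajectory parameters. Marker gene `g` has mean log2 abundance
#' `b_g + a_g * f_g((t - tau_i) / w_g)` at sampling time `t`, where `tau_i`
#' is patient `i`'s true WOI center and the shape `f_g` is either a Gaussian
#' bump or a logistic switch; background genes are time-constant. Expression
#' is materialized later by [sample_biopsies()], so one cohort can be
#' biopsied at arbitrary time points.
#'
#' @param config A [cohort_config()].
#' @return An object of class `woi_cohort`: a list with `truth` (data frame
#'   of `patient_id`, `true_woi_center`, `displacement_hours`),
#'   `gene_params` (per-gene trajectory parameters), `gene_ids`, and the
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    receptive <- stats::runif(n) < config$receptive_fraction
    delay <- stats::runif(n, config$delay_min, config$delay_max)
    if (config$signed_displacement) {
      delay <- delay * sample(c(-1, 1), n, replace = TRUE)
    }
    displacement <- ifelse(receptive, 0, delay)
    truth <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      true_woi_center = config$reference_woi_hours + displacement,
      displacement_hours = displacement,
      stringsAsFactors = FALSE)

    g <- config$n_genes
    m <- config$n_markers
    gene_params <- data.frame(
      gene_id = sprintf("G%05d", seq_len(g)),
      is_marker = seq_len(g) <= m,
      shape = "constant",
      baseline = stats::runif(g, 2, 8),
      amplitude = 0,
      width = 24,
      stringsAsFactors = FALSE)
    if (m > 0L) {
      gene_params$shape[seq_len(m)] <-
        sample(c("bump", "switch"), m, replace = TRUE)
      gene_params$amplitude[seq_len(m)] <-
        stats::runif(m, 1, 3) * sample(c(-1, 1), m, replace = TRUE)
      gene_params$width[seq_len(m)] <- stats::runif(m, 18, 48)
    }
  })
  structure(list(truth = truth, gene_params = gene_params,
                 gene_ids = gene_params$gene_id, config = config),
            class = "woi_cohort")
}

#' @export
print.woi_cohort <- function(x, ...) {
  cat("Synthetic WOI cohort:", nrow(x$truth), "patients,",
      x$config$n_genes, "genes (", x$config$n_markers, "markers )\n")
  cat(sprintf("  receptive (zero displacement): %d/%d\n",
              sum(x$truth$displacement_hours == 0), nrow(x$truth)))
  invisible(x)
}

# mean log2 abundance of every gene at time t for one patient (tau = WOI center)
marker_mean_matrix <- function(gene_params, t, tau) {
  u <- (t - tau) / gene_params$width
  shape_val <- ifelse(gene_params$shape == "bump", exp(-u^2 / 2),
                      ifelse(gene_params$shape == "switch",
                             stats::plogis(u), 0))
  gene_params$baseline + gene_params$amplitude * shape_val
}

#' Draw endometrial biopsies from a synthetic cohort
#'
#' Materializes one expression sample per patient per requested sampling
#' time. Deterministic: the same call on the same cohort returns
#' bit-identical output (noise is seeded from the cohort seed and the
#' requested times).
#'
#' @param cohort A [generate_cohort()] result.
#' @param times Sampling times in hours after the first progesterone
#'   administration, e.g. `c(72, 120, 168)` for P+3/P+5/P+7.
#' @return An object of class `woi_expr`: list with `matrix` (genes x
#'   samples, log2 scale or counts per the config) and `meta` (data frame
#'   of `sample_id`, `patient_id`, `sampling_time`).
#' @export
sample_biopsies <- function(cohort, times) {
  stopifnot(inherits(cohort, "woi_cohort"))
  if (length(times) == 0L) stop("'times' must be non-empty", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("sampling times must be finite and nonnegative", call. = FALSE)
  }
  cfg <- cohort$config
  # deterministic sub-seed: cohort seed + a small hash of the time grid
  sub <- (cfg$seed + sum((seq_along(times) * 131L) %%
                           97003L * (round(times) %% 9973L))) %% 2147483629
  truth <- cohort$truth
  n <- nrow(truth)
  meta <- data.frame(
    sample_id = sprintf("%s_T%03d", rep(truth$patient_id, times = length(times)),
                        rep(round(times), each = n)),
    patient_id = rep(truth$patient_id, times = length(times)),
    sampling_time = rep(times, each = n),
    stringsAsFactors = FALSE)
  mat <- matrix(0, nrow = cfg$n_genes, ncol = nrow(meta),
                dimnames = list(cohort$gene_ids, meta$sample_id))
  withr::with_seed(as.integer(sub), {
    for (j in seq_len(nrow(meta))) {
      i <- match(meta$patient_id[j], truth$patient_id)
      mu <- marker_mean_matrix(cohort$gene_params, meta$sampling_time[j],
                               truth$true_woi_center[i])
      if (cfg$noise_sd > 0) {
        mu <- mu + stats::rnorm(cfg$n_genes, sd = cfg$noise_sd)
      }
      if (cfg$scale == "counts") {
        mat[, j] <- stats::rnbinom(cfg$n_genes, mu = 2^mu, size = cfg$nb_size)
      } else {
        mat[, j] <- mu
      }
    }
  })
  structure(list(matrix = mat, meta = meta), class = "woi_expr")
}

#' Three-point (P+3, P+5, P+7) biopsy set
#' @param cohort A [generate_cohort()] result.
#' @return A `woi_expr` with three samples per patient.
#' @export
three_point_biopsies <- function(cohort) sample_biopsies(cohort, c(72, 120, 168))

#' Single-point (P+5) biopsy set
#' @param cohort A [generate_cohort()] result.
#' @return A `woi_expr` with one sample per patient.
#' @export
one_point_biopsies <- function(cohort) sample_biopsies(cohort, 120)

#' Simulate pregnancy outcomes of embryo transfers
#'
#' Clinical pregnancy occurs with probability
#' `p_max * exp(-((transfer - woi_center) / decay_scale)^2)`; among
#' hCG-positive cycles a fraction `p_bio_given_hcg` end as biochemical
#' pregnancies. Flags are nested: clinical implies hCG-positive;
#' biochemical implies hCG-positive and not clinical.
#'
#' @param truth Data frame with columns `patient_id` and `true_woi_center`
#'   (e.g. the `truth` element of a [generate_cohort()] result).
#' @param transfer_time Transfer time(s), hours after the first progesterone
#'   administration; length 1 or `nrow(truth)`.
#' @param params A [cohort_config()] (only the outcome parameters are used),
#'   or any list with `p_max`, `p_bio_given_hcg`, `decay_scale_hours`.
#' @param seed Integer seed for the outcome draws.
#' @return Data frame: `patient_id`, `transfer_time`, and logical `hcg`,
#'   `biochemical`, `clinical`.
#' @export
simulate_transfer_outcome <- function(truth, transfer_time, params,
                                      seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("patient_id", "true_woi_center")
                                      %in% names(truth)))
  p_max <- params$p_max
  r <- params$p_bio_given_hcg
  decay <- params$decay_scale_hours
  if (!is.numeric(p_max) || p_max < 0 || p_max > 1) {
    stop("p_max must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(transfer_time)) || any(transfer_time < 0)) {
    stop("transfer_time must be finite and >= 0", call. = FALSE)
  }
  n <- nrow(truth)
  transfer_time <- rep_len(transfer_time, n)
  delta <- transfer_time - truth$true_woi_center
  z <- if (is.infinite(decay)) rep(0, n) else (delta / decay)^2
  p_clin <- p_max * exp(-z)
  p_bio <- pmin(p_clin * r / (1 - r), 1 - p_clin)
  withr::with_seed(as.integer(seed), u <- stats::runif(n))
  clinical <- u < p_clin
  biochemical <- !clinical & u < (p_clin + p_bio)
  data.frame(patient_id = truth$patient_id,
             transfer_time = transfer_time,
             hcg = clinical | biochemical,
             biochemical = biochemical,
             clinical = clinical,
             stringsAsFactors = FALSE)
}

#' Write a cohort's expression matrix, metadata and truth table to disk
#'
#' The expression matrix is written as tab-delimited text (genes in rows,
#' sample ids in the header); metadata and truth as CSV.
#'
#' @param expr A `woi_expr` from [sample_biopsies()].
#' @param truth The cohort truth data frame (optional).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(expr, truth = NULL, dir) {
  stopifnot(inherits(expr, "woi_expr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             meta = file.path(dir, "meta.csv"))
  write_matrix_tsv(expr$matrix, paths[["matrix"]])
  utils::write.csv(expr$meta, paths[["meta"]], row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Write / read a gene-by-sample matrix as tab-delimited text
#' @param mat Numeric matrix, genes in rows, named dimensions.
#' @param path File path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
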