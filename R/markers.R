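#' Rank genes by association with the hour label
#'
#' A light-weight marker screen standing in for a full differential-
#' expression pipeline: each gene is scored by its one-way ANOVA F
#' statistic across the discrete label groups, and the top `k` genes are
#' kept. Because training labels live on a 9-point grid, a grouped F test
#' is preferred over correlation with the continuous label.
#'
#' @param mat Gene-by-sample numeric matrix (log-scale abundances; rows
#'   named by gene id).
#' @param labels Hour label per sample (column), any discrete coding.
#' @param k Panel size. Default 175. If `k >= nrow(mat)` all genes are
#'   returned, ordered by F.
#' @return An object of class `marker_panel`: data frame with `gene_id` and
#'   `score` (F statistic), sorted by decreasing score; ties broken by
#'   gene id.
#' @export
select_markers <- function(mat, labels, k = 175L) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) != length(labels)) {
    stop("matrix columns must align with labels", call. = FALSE)
  }
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  f <- factor(labels)
  g <- nlevels(f)
  if (g < 2L) stop("need at least 2 distinct label groups", call. = FALSE)
  n <- ncol(mat)
  if (n <= g) stop("need more samples than label groups", call. = FALSE)

  counts <- tabulate(f, nbins = g)
  ind <- stats::model.matrix(~ f - 1)           # n x g indicator
  gsum <- mat %*% ind                           # per-gene group sums
  gmean <- sweep(gsum, 2, counts, "/")
  grand <- rowMeans(mat)
  ssb <- rowSums(sweep(gmean - grand, 2, counts, "*") * (gmean - grand))
  sst <- rowSums((mat - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  eps <- 1e-12 * pmax(sst, 1)
  fstat <- ifelse(sst < 1e-12, 0,
                  ifelse(ssw < eps, Inf,
                         (ssb / (g - 1)) / (ssw / (n - g))))
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("G%05d", seq_len(nrow(mat)))
  ord <- order(-fstat, ids)
  keep <- ord[seq_len(min(k, nrow(mat)))]
  structure(data.frame(gene_id = ids[keep], score = fstat[keep],
                       stringsAsFactors = FALSE),
            class = c("marker_panel", "data.frame"))
}

#' Write / read a marker panel as two-column CSV
#' @param panel A [select_markers()] result.
#' @param path File path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns the
#'   panel.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("marker_panel", "data.frame"))
}
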