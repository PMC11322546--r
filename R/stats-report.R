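#' @include shape-metrics.R
NULL

#' Normalise measurements by the reference genotype's median
#'
#' Within each experiment, every value of \code{measure} is divided by
#' the median of that measure in the reference genotype of the same
#' experiment (so the reference normalises to median 1 per experiment,
#' and experiments with different absolute scales become comparable).
#'
#' @param records morphometric (or other) record data.frame with columns
#'   \code{genotype}, \code{experiment_id} and \code{measure}
#' @param referenceGenotype genotype supplying the per-experiment median
#' @param measure column to normalise
#' @return the records with added columns \code{reference_median} and
#'   \code{normalized}
#' @export
normalizeByReference <- function(records, referenceGenotype, measure) {
  stopifnot(measure %in% names(records))
  out <- do.call(rbind, lapply(split(records, records$experiment_id),
    function(e) {
      ref <- e[e$genotype == referenceGenotype, measure]
      if (!length(ref))
        stop("experiment ", e$experiment_id[1L],
             " lacks records of the reference genotype ",
             referenceGenotype)
      m <- stats::median(ref)
      if (!is.finite(m) || m <= 0)
        stop("non-positive reference median in experiment ",
             e$experiment_id[1L])
      e$reference_median <- m
      e$normalized <- e[[measure]] / m
      e
    }))
  rownames(out) <- NULL
  out
}

#' Two-genotype comparison at one timepoint (Mann-Whitney-Wilcoxon)
#'
#' Two-sided rank-sum test between two genotypes' values of one measure
#' at one timepoint: exact p for small groups (both n <= 8, no ties),
#' normal approximation with continuity and tie correction otherwise. No
#' multiplicity correction is applied across timepoints.
#'
#' @param records record data.frame
#' @param measure column to compare
#' @param timepoint timepoint (days) to subset
#' @param genotypes character(2); defaults to the two genotypes present
#' @param alpha significance level for the flag (default 0.05)
#' @return one-row data.frame: grouping, test, statistic (U), p_value,
#'   significant, n1, n2
#' @export
compareGenotypes <- function(records, measure, timepoint,
                             genotypes = NULL, alpha = 0.05) {
  stopifnot(measure %in% names(records))
  sub <- records[records$timepoint_d == timepoint, ]
  if (is.null(genotypes)) genotypes <- unique(sub$genotype)
  if (length(genotypes) != 2L)
    stop("exactly two genotypes are required")
  x <- sub[sub$genotype == genotypes[1L], measure]
  y <- sub[sub$genotype == genotypes[2L], measure]
  if (!length(x) || !length(y)) stop("a group is empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 8L && length(y) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  data.frame(
    grouping = paste0("timepoint ", timepoint, ": ", genotypes[1L],
                      " vs ", genotypes[2L]),
    test = if (exact) "Mann-Whitney-Wilcoxon (exact)" else
      "Mann-Whitney-Wilcoxon (normal approx., tie-corrected)",
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    significant = wt$p.value < alpha,
    n1 = length(x), n2 = length(y))
}

# Insert-and-absorb compact letter display over a symmetric p matrix.
# Guarantees: groups sharing a letter have pairwise p >= alpha; groups
# sharing no letter have p < alpha.
.insertAbsorb <- function(pmat, alpha = 0.05) {
  k <- nrow(pmat)
  sets <- list(seq_len(k))
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      i <- sig[r, 1L]; j <- sig[r, 2L]
      nxt <- list()
      for (s in sets) {
        if (i %in% s && j %in% s)
          nxt <- c(nxt, list(setdiff(s, i)), list(setdiff(s, j)))
        else nxt <- c(nxt, list(s))
      }
      nxt <- Filter(length, nxt)
      # absorb sets contained in another (and duplicates)
      keep <- rep(TRUE, length(nxt))
      for (a in seq_along(nxt)) {
        if (!keep[a]) next
        for (b in seq_along(nxt)) {
          if (a == b || !keep[b]) next
          if (all(nxt[[a]] %in% nxt[[b]]) &&
              (length(nxt[[a]]) < length(nxt[[b]]) || a > b))
            keep[a] <- FALSE
        }
      }
      sets <- nxt[keep]
    }
  }
  sets <- sets[order(vapply(sets, min, 0L))]
  labels <- vapply(seq_len(k), function(g)
    paste0(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
           collapse = ""), "")
  stats::setNames(labels, rownames(pmat))
}

#' Across-timepoint comparison: one-way ANOVA with Tukey letters
#'
#' Classic (equal-variance) one-way ANOVA of one measure across
#' timepoints within a genotype, followed by Tukey HSD pairwise
#' comparisons and a compact letter display (insert-and-absorb over the
#' Tukey p matrix): timepoints sharing a letter do not differ
#' significantly at \code{alpha}. The letter invariants are asserted on
#' every output.
#'
#' @param records record data.frame
#' @param measure column to compare
#' @param genotype genotype to subset
#' @param alpha significance level (default 0.05)
#' @return list: \code{anova} (one-row data.frame with F and p),
#'   \code{tukey_p} (symmetric pairwise p matrix), \code{letters} (named
#'   character, one per timepoint), \code{alpha}
#' @export
compareTimepoints <- function(records, measure, genotype, alpha = 0.05) {
  stopifnot(measure %in% names(records))
  sub <- records[records$genotype == genotype, ]
  sub$tp <- factor(sub$timepoint_d)
  cnt <- table(sub$tp)
  if (length(cnt) < 2L) stop("need at least two timepoints")
  if (any(cnt < 2L))
    stop("each timepoint needs n >= 2 for the ANOVA: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  fml <- stats::as.formula(paste(measure, "~ tp"))
  fit <- stats::aov(fml, data = sub)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$tp
  lev <- levels(sub$tp)
  pmat <- matrix(NA_real_, length(lev), length(lev),
                 dimnames = list(lev, lev))
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(prs)) {
    a <- prs[[r]][1L]; b <- prs[[r]][2L]
    pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
  }
  ltr <- .insertAbsorb(pmat, alpha)
  # assert the display invariants
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    if (a >= b) next
    shared <- length(intersect(strsplit(ltr[a], "")[[1L]],
                               strsplit(ltr[b], "")[[1L]])) > 0L
    if (shared && pmat[a, b] < alpha)
      stop("letter display violated: shared letter with p < alpha")
    if (!shared && pmat[a, b] >= alpha)
      stop("letter display violated: no shared letter with p >= alpha")
  }
  list(
    anova = data.frame(F = an[1L, "F value"], p_value = an[1L, "Pr(>F)"],
                       df_between = an[1L, "Df"], df_within = an[2L, "Df"]),
    tukey_p = pmat, letters = ltr, alpha = alpha)
}

#' Fold change of medians between two timepoints
#'
#' \code{median(measure at t1) / median(measure at t0)}, optionally within
#' one genotype.
#'
#' @param records record data.frame
#' @param measure column
#' @param t0,t1 timepoints (days)
#' @param genotype optional genotype subset
#' @return the ratio (single number)
#' @export
foldChange <- function(records, measure, t0, t1, genotype = NULL) {
  stopifnot(measure %in% names(records))
  if (!is.null(genotype)) records <- records[records$genotype == genotype, ]
  v0 <- records[records$timepoint_d == t0, measure]
  v1 <- records[records$timepoint_d == t1, measure]
  if (!length(v0) || !length(v1)) stop("both timepoints must be populated")
  m0 <- stats::median(v0)
  if (m0 == 0) stop("zero median at t0")
  stats::median(v1) / m0
}
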