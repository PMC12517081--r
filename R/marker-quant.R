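#' Background-subtracted mean ROI intensity
#'
#' The marker readout per cell: mean intensity over the ROI minus the mean
#' over a disjoint background region.
#'
#' @param image numeric intensity matrix.
#' @param roi logical/label matrix selecting the cell pixels.
#' @param background logical/label matrix selecting the background region.
#' @return data.frame with raw_mean, background_mean, corrected.
#' @export
measureRoiIntensity <- function(image, roi, background) {
  roi <- roi > 0; background <- background > 0
  if (!any(roi)) stop("empty ROI")
  if (!any(background)) stop("empty background region")
  if (any(roi & background)) stop("ROI and background region overlap")
  raw <- mean(image[roi])
  bg <- mean(image[background])
  data.frame(raw_mean = raw, background_mean = bg, corrected = raw - bg)
}

#' Per-cell marker measurements for a labelled mask image
#'
#' Applies [measureRoiIntensity()] to every labelled cell against a common
#' background region (all unlabelled pixels by default).
#'
#' @param image numeric intensity matrix.
#' @param cellMasks integer label matrix.
#' @param background optional explicit background mask; defaults to all
#'   pixels with label 0.
#' @param condition,marker,image_id optional labels stored with each row.
#' @return data.frame: cell_id, condition, marker, image_id, raw_mean,
#'   background_mean, corrected.
#' @export
measureCellIntensities <- function(image, cellMasks, background = NULL,
                                   condition = NA_character_,
                                   marker = NA_character_, image_id = 1L) {
  ids <- setdiff(sort(unique(as.vector(cellMasks))), 0L)
  if (!length(ids)) stop("no labelled cells")
  if (is.null(background)) background <- cellMasks == 0L
  rows <- lapply(ids, function(id) {
    m <- measureRoiIntensity(image, cellMasks == id, background & !(cellMasks == id))
    cbind(data.frame(cell_id = id, condition = condition, marker = marker,
                     image_id = image_id), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize corrected intensities to a reference (M0) condition
#'
#' Divides each corrected intensity by the mean corrected intensity of the
#' matched reference group, matching on every column named in \code{by}
#' (substrate and marker by default, so each substrate/marker combination is
#' normalized to its own M0).
#'
#' @param measurements data.frame with columns \code{corrected},
#'   \code{phenotype}, and the matching columns in \code{by}.
#' @param reference phenotype label of the reference group (default "M0").
#' @param by character vector of matching columns present in
#'   \code{measurements} (columns absent from the data are ignored).
#' @return the input with a \code{normalized} column appended.
#' @export
normalizeToReference <- function(measurements, reference = "M0",
                                 by = c("substrate", "marker")) {
  stopifnot(all(c("corrected", "phenotype") %in% names(measurements)))
  by <- intersect(by, names(measurements))
  key <- if (length(by)) interaction(measurements[by], drop = FALSE)
         else factor(rep("all", nrow(measurements)))
  out <- measurements
  out$normalized <- NA_real_
  for (k in levels(factor(key))) {
    sel <- key == k
    ref <- sel & measurements$phenotype == reference
    if (!any(ref))
      stop(sprintf("no matched reference '%s' measurements for condition '%s'",
                   reference, k))
    refMean <- mean(measurements$corrected[ref])
    if (refMean <= 0)
      stop(sprintf("reference mean for condition '%s' is not positive", k))
    out$normalized[sel] <- measurements$corrected[sel] / refMean
  }
  empty <- setdiff(unique(measurements$phenotype), c(reference))
  for (ph in empty) if (!any(measurements$phenotype == ph))
    warning(sprintf("phenotype group '%s' is empty", ph))
  out
}

#' Percentage induction efficiency
#'
#' A cell counts as marker-positive when its background-corrected intensity
#' strictly exceeds \code{threshold} times the mean corrected intensity of
#' the matched reference (M0) group. Efficiency is 100 x positives / total,
#' computed per image and then averaged (default) or pooled over all cells.
#'
#' @param measurements data.frame as in [normalizeToReference()], with an
#'   \code{image_id} column for the per-image mode.
#' @param reference reference phenotype label (default "M0").
#' @param by matching columns, as in [normalizeToReference()].
#' @param threshold positivity threshold as a multiple of the reference mean
#'   (default 1).
#' @param perImage average per-image efficiencies (default TRUE) or pool.
#' @return data.frame with one row per non-reference phenotype (and matching
#'   condition): phenotype, the matching columns, and \code{efficiency} in
#'   percent (always within [0, 100]).
#' @export
inductionEfficiency <- function(measurements, reference = "M0",
                                by = c("substrate", "marker"),
                                threshold = 1, perImage = TRUE) {
  stopifnot(all(c("corrected", "phenotype") %in% names(measurements)))
  if (!nrow(measurements)) stop("no cells measured")
  by <- intersect(by, names(measurements))
  key <- if (length(by)) interaction(measurements[by], drop = FALSE)
         else factor(rep("all", nrow(measurements)))
  res <- list()
  for (k in levels(factor(key))) {
    sel <- key == k
    ref <- sel & measurements$phenotype == reference
    if (!any(ref))
      stop(sprintf("no matched reference '%s' for condition '%s'", reference, k))
    refMean <- mean(measurements$corrected[ref])
    for (ph in setdiff(unique(measurements$phenotype[sel]), reference)) {
      g <- measurements[sel & measurements$phenotype == ph, , drop = FALSE]
      if (!nrow(g)) stop("zero cells in group")
      pos <- g$corrected > threshold * refMean
      eff <- if (perImage && "image_id" %in% names(g)) {
        mean(tapply(pos, g$image_id, function(p) 100 * mean(p)))
      } else {
        100 * mean(pos)
      }
      row <- data.frame(phenotype = ph, efficiency = eff)
      for (b in by) row[[b]] <- g[[b]][1]
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Significance stars at the conventional thresholds
#'
#' @param p numeric p-values.
#' @return character: "****" p < 0.0001, "***" p < 0.001, "**" p < 0.01,
#'   "*" p < 0.05, "ns" otherwise.
#' @export
significanceStars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Dunn's post-hoc test of pairwise rank differences
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis omnibus, with
#' tie correction, adjusted for multiple comparisons.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @param adjust p-value adjustment method (default "holm"; "bonferroni"
#'   also conventional).
#' @return data.frame: group1, group2, z, p_adj.
#' @export
dunnTest <- function(values, groups, adjust = "holm") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tie <- table(r)
  tieCorr <- sum(tie^3 - tie) / (12 * (N - 1))
  lev <- levels(groups)
  meanR <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  cmb <- utils::combn(lev, 2)
  z <- apply(cmb, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) *
                 (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    (meanR[[pr[1]]] - meanR[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = z,
             p_adj = stats::p.adjust(p, method = adjust))
}

#' Normality-gated group comparison
#'
#' The two-branch comparison scheme: Shapiro-Wilk normality per group at
#' \code{alpha}; if every group passes, ordinary one-way ANOVA with Tukey's
#' multiple-comparison post-hoc, otherwise Kruskal-Wallis with Dunn's
#' post-hoc. Pairwise adjusted p-values carry significance stars at
#' 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 groups, each n >= 3).
#' @param alpha significance level for the normality gate and stars.
#' @param branch "auto" (normality-gated), or force "parametric" /
#'   "nonparametric".
#' @param adjust adjustment for Dunn's test (default "holm").
#' @return a \linkS4class{GroupComparison}.
#' @examples
#' set.seed(1)
#' compareGroups(c(rnorm(10), rnorm(10, 3)), rep(c("a", "b"), each = 10))
#' @export
compareGroups <- function(values, groups, alpha = 0.05,
                          branch = c("auto", "parametric", "nonparametric"),
                          adjust = "holm") {
  branch <- match.arg(branch)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  n <- tapply(values, groups, length)
  if (any(is.na(n)) || any(n < 3)) stop("every group must have n >= 3")
  normP <- tapply(values, groups, function(v) {
    if (length(unique(v)) < 3) return(0)
    stats::shapiro.test(v)$p.value
  })
  normality <- normP >= alpha
  useParam <- switch(branch,
                     auto = all(normality),
                     parametric = TRUE,
                     nonparametric = FALSE)
  df <- data.frame(v = values, g = groups)
  if (useParam) {
    fit <- stats::aov(v ~ g, data = df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    prs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairs <- data.frame(group1 = vapply(prs, `[`, "", 1),
                        group2 = vapply(prs, `[`, "", 2),
                        p_adj = tk[, "p adj"])
    testUsed <- "ANOVA+Tukey"
    statistic <- an[["F value"]][1]
    omnibusP <- an[["Pr(>F)"]][1]
  } else {
    kw <- stats::kruskal.test(v ~ g, data = df)
    pairs <- dunnTest(values, groups, adjust = adjust)[
      , c("group1", "group2", "p_adj")]
    testUsed <- "KruskalWallis+Dunn"
    statistic <- unname(kw$statistic)
    omnibusP <- kw$p.value
  }
  pairs$stars <- significanceStars(pairs$p_adj)
  rownames(pairs) <- NULL
  new("GroupComparison", testUsed = testUsed, statistic = statistic,
      omnibusP = omnibusP, pairs = pairs,
      normality = stats::setNames(as.logical(normality), names(normality)),
      alpha = alpha)
}
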