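#' Normality gate for the parametric/nonparametric branch choice
#'
#' Shapiro-Wilk at `alpha` per group; the parametric branch is taken only
#' if every group passes. Degenerate inputs (n < 3 or a constant vector)
#' default to the nonparametric branch with a note.
#'
#' @param values numeric vector of observations.
#' @param groups optional factor/character of the same length; `NULL`
#'   treats `values` as a single group.
#' @param alpha gate level (default 0.05).
#' @return list with `decision` (`"parametric"`/`"nonparametric"`),
#'   `pValues` (named, per group; `NA` where degenerate) and `notes`.
#' @examples
#' normalityGate(rnorm(50))$decision
#' @export
normalityGate <- function(values, groups = NULL, alpha = 0.05) {
  if (is.null(groups)) groups <- rep("all", length(values))
  sp <- split(values, groups)
  notes <- character()
  p <- vapply(names(sp), function(g) {
    x <- sp[[g]]
    if (length(x) < 3L) {
      notes <<- c(notes, paste0("group ", g, ": n < 3, nonparametric by default"))
      return(NA_real_)
    }
    if (stats::var(x) == 0) {
      notes <<- c(notes, paste0("group ", g, ": constant values, nonparametric"))
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  decision <- if (length(p) && all(!is.na(p)) && all(p > alpha))
    "parametric" else "nonparametric"
  list(decision = decision, pValues = p, notes = notes)
}

.checkRecordCols <- function(records, cols) {
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
}

#' Paired PL/NPL comparison per group and variable
#'
#' Pairs the polarized and non-polarized record of each lesion and tests
#' the within-pair difference per group: paired t when the normality gate
#' passes for both illumination vectors, Wilcoxon signed-rank otherwise.
#' Unpaired lesions are excluded with a note.
#'
#' @param records data.frame with columns `lesion_id`, `group`,
#'   `illumination` (`"PL"`/`"NPL"`) and the measurement `variable`.
#' @param variable name of the measurement column (e.g. `"shape_fd"`).
#' @param alpha normality-gate level.
#' @return a [StatsReport-class]; `summary` holds per-group means/SDs
#'   under each illumination, n and the mean PL - NPL difference,
#'   `pValues` one p per group.
#' @export
pairedIlluminationTest <- function(records, variable, alpha = 0.05) {
  .checkRecordCols(records, c("lesion_id", "group", "illumination", variable))
  notes <- character()
  rows <- list(); pv <- numeric(0); tests <- character()
  for (g in unique(records$group)) {
    rg <- records[records$group == g, ]
    wide <- merge(rg[rg$illumination == "PL", c("lesion_id", variable)],
                  rg[rg$illumination == "NPL", c("lesion_id", variable)],
                  by = "lesion_id", suffixes = c("_PL", "_NPL"))
    dropped <- sum(table(rg$lesion_id) != 2L)
    if (dropped > 0) {
      warning(dropped, " unpaired lesion(s) excluded in group ", g)
      notes <- c(notes, paste0("group ", g, ": ", dropped, " unpaired excluded"))
    }
    x <- wide[[paste0(variable, "_PL")]]
    y <- wide[[paste0(variable, "_NPL")]]
    gate <- normalityGate(c(x, y), rep(c("PL", "NPL"), c(length(x), length(y))),
                          alpha)
    if (length(x) < 2L) {
      p <- NA_real_
      test <- "degenerate (fewer than 2 pairs)"
      notes <- c(notes, paste0("group ", g, ": fewer than 2 pairs, no test"))
    } else if (identical(x, y) || stats::var(x - y) == 0) {
      p <- if (all(x == y)) 1 else NA_real_
      test <- "degenerate (zero-variance difference)"
    } else if (gate$decision == "parametric") {
      p <- stats::t.test(x, y, paired = TRUE)$p.value
      test <- "paired t"
    } else {
      p <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
      test <- "Wilcoxon signed-rank"
    }
    pv[g] <- p
    tests <- c(tests, test)
    rows[[g]] <- data.frame(group = g, variable = variable, n = length(x),
                            mean_PL = mean(x), sd_PL = stats::sd(x),
                            mean_NPL = mean(y), sd_NPL = stats::sd(y),
                            mean_diff = mean(x - y), test = test, p = p)
  }
  summ <- do.call(rbind, rows)
  new("StatsReport", test = paste(unique(tests), collapse = " / "),
      decision = "per-group gate",
      summary = if (is.null(summ)) data.frame() else summ,
      pairwise = list(), pValues = pv, notes = notes)
}

# Fisher least-significant-difference pairwise p-values after one-way
# ANOVA: pairwise t statistics on the pooled residual mean square, no
# family-wise adjustment.
.lsdPairwise <- function(values, groups) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  lv <- levels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  out <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    tstat <- (m[i] - m[j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
    out[i, j] <- out[j, i] <- 2 * stats::pt(-abs(tstat), stats::df.residual(fit))
  }
  list(p = out, omnibus = summary(fit)[[1]][["Pr(>F)"]][1])
}

# Dunn-type multiple comparison of mean ranks after Kruskal-Wallis, with
# tie correction and Bonferroni adjustment capped at 1 (reproducing the
# "p = 1.000000" cells of spreadsheet outputs).
.dunnPairwise <- function(values, groups) {
  groups <- factor(groups)
  rk <- rank(values)
  N <- length(values)
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  n <- tapply(rk, groups, length)
  mr <- tapply(rk, groups, mean)
  mComp <- length(lv) * (length(lv) - 1) / 2
  out <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    if (n[i] < 3L || n[j] < 3L) next  # cell unavailable
    z <- (mr[i] - mr[j]) /
      sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[i] + 1 / n[j]))
    out[i, j] <- out[j, i] <- min(1, 2 * stats::pnorm(-abs(z)) * mComp)
  }
  list(p = out, meanRanks = mr)
}

#' Multi-group comparison of one measurement
#'
#' Normality-gated three-group (MM/DN/BN) comparison: one-way ANOVA with
#' Fisher LSD pairwise post hocs on the parametric branch, Kruskal-Wallis
#' with Dunn-type mean-rank comparisons (Bonferroni-adjusted, capped at 1)
#' on the nonparametric branch. When records carry both illuminations a
#' named list of reports (one per illumination) is returned.
#'
#' @param records data.frame with columns `group`, `illumination` and the
#'   measurement `variable`.
#' @param variable name of the measurement column.
#' @param alpha normality-gate level.
#' @return a [StatsReport-class], or a named list of them (one per
#'   illumination present).
#' @export
groupComparison <- function(records, variable, alpha = 0.05) {
  .checkRecordCols(records, c("group", "illumination", variable))
  ills <- unique(records$illumination)
  if (length(ills) > 1L) {
    out <- lapply(ills, function(il)
      groupComparison(records[records$illumination == il, ], variable, alpha))
    names(out) <- ills
    return(out)
  }
  v <- records[[variable]]
  g <- factor(records$group)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  counts <- table(g)
  if (any(counts < 3L))
    warning("group(s) with n < 3: ",
            paste(names(counts)[counts < 3L], collapse = ", "),
            "; their pairwise cells are unavailable")
  gate <- normalityGate(v, g, alpha)
  if (gate$decision == "parametric") {
    res <- .lsdPairwise(v, g)
    summ <- data.frame(group = levels(g), n = as.integer(counts),
                       mean = as.numeric(tapply(v, g, mean)),
                       sd = as.numeric(tapply(v, g, stats::sd)))
    new("StatsReport", test = "one-way ANOVA + Fisher LSD",
        decision = "parametric", summary = summ,
        pairwise = list(p = res$p),
        pValues = c(omnibus = res$omnibus), notes = gate$notes)
  } else {
    kw <- stats::kruskal.test(v, g)
    res <- .dunnPairwise(v, g)
    summ <- data.frame(group = levels(g), n = as.integer(counts),
                       mean = as.numeric(tapply(v, g, mean)),
                       sd = as.numeric(tapply(v, g, stats::sd)),
                       mean_rank = as.numeric(res$meanRanks))
    new("StatsReport",
        test = "Kruskal-Wallis + Dunn mean ranks (Bonferroni)",
        decision = "nonparametric", summary = summ,
        pairwise = list(p = res$p),
        pValues = c(omnibus = kw$p.value), notes = gate$notes)
  }
}

#' Spearman correlation of shape FD with area and perimeter
#'
#' Per group and illumination, the Spearman rank correlation of the shape
#' fractal dimension against lesion area and perimeter. Groups with fewer
#' than `minN` lesions, or tie-only vectors, are reported as `NA` with a
#' note.
#'
#' @param records data.frame with columns `group`, `illumination`,
#'   `shape_fd`, `area`, `perimeter`.
#' @param minN minimum lesions per group x illumination cell (default 5).
#' @return data.frame with columns `group`, `illumination`, `against`,
#'   `r`, `n`.
#' @export
correlationMatrix <- function(records, minN = 5L) {
  .checkRecordCols(records, c("group", "illumination", "shape_fd",
                              "area", "perimeter"))
  out <- list()
  for (g in unique(records$group)) for (il in unique(records$illumination)) {
    rg <- records[records$group == g & records$illumination == il, ]
    for (ag in c("area", "perimeter")) {
      r <- NA_real_
      if (nrow(rg) >= minN &&
          stats::var(rg$shape_fd) > 0 && stats::var(rg[[ag]]) > 0)
        r <- stats::cor(rg$shape_fd, rg[[ag]], method = "spearman")
      out[[length(out) + 1L]] <- data.frame(
        group = g, illumination = il, against = ag, r = r, n = nrow(rg))
    }
  }
  do.call(rbind, out)
}

#' Melanoma in-situ versus invasive subgroup tests
#'
#' Within the melanoma group, compares the in-situ and invasive subgroups
#' per illumination: unpaired Student t on the per-lesion shape FD and
#' Mann-Whitney U on the per-ROI surface FD. An empty subgroup renders the
#' corresponding report unavailable (`NA` p with a note).
#'
#' @param shapeRecords data.frame with columns `group`, `stage`
#'   (`"in_situ"`/`"invasive"`), `illumination`, `shape_fd`.
#' @param surfaceRecords optional data.frame with columns `group`,
#'   `stage`, `illumination`, `surface_fd` (one row per ROI).
#' @return a [StatsReport-class] with one summary row and one p-value per
#'   variable x illumination.
#' @export
melanomaSubgroupTest <- function(shapeRecords, surfaceRecords = NULL) {
  .checkRecordCols(shapeRecords, c("group", "stage", "illumination", "shape_fd"))
  run <- function(df, variable, testName) {
    rows <- list(); pv <- numeric(0); notes <- character()
    mm <- df[df$group == "MM" & df$stage %in% c("in_situ", "invasive"), ]
    for (il in unique(mm$illumination)) {
      x <- mm[mm$illumination == il & mm$stage == "in_situ", variable]
      y <- mm[mm$illumination == il & mm$stage == "invasive", variable]
      key <- paste(variable, il, sep = "_")
      if (length(x) < 2L || length(y) < 2L) {
        notes <- c(notes, paste0(key, ": a subgroup is empty or too small"))
        pv[key] <- NA_real_
        next
      }
      p <- if (testName == "t") stats::t.test(x, y, var.equal = TRUE)$p.value
           else stats::wilcox.test(x, y, exact = FALSE)$p.value
      pv[key] <- p
      rows[[key]] <- data.frame(
        variable = variable, illumination = il,
        mean_in_situ = mean(x), sd_in_situ = stats::sd(x), n_in_situ = length(x),
        mean_invasive = mean(y), sd_invasive = stats::sd(y),
        n_invasive = length(y), p = p)
    }
    list(rows = rows, pv = pv, notes = notes)
  }
  shp <- run(shapeRecords, "shape_fd", "t")
  srf <- if (!is.null(surfaceRecords)) {
    .checkRecordCols(surfaceRecords, c("group", "stage", "illumination",
                                       "surface_fd"))
    run(surfaceRecords, "surface_fd", "mw")
  } else list(rows = list(), pv = numeric(0), notes = character())
  summ <- do.call(rbind, c(shp$rows, srf$rows))
  new("StatsReport",
      test = "unpaired t (shape FD) / Mann-Whitney U (surface FD)",
      decision = "fixed per variable",
      summary = if (is.null(summ)) data.frame() else summ,
      pairwise = list(), pValues = c(shp$pv, srf$pv),
      notes = c(shp$notes, srf$notes))
}

setMethod("show", "StatsReport", function(object) {
  cat("StatsReport:", object@test, "[", object@decision, "]\n")
  print(object@summary, row.names = FALSE)
  if (length(object@pValues)) {
    cat("p-values:\n")
    print(object@pValues)
  }
  for (m in object@pairwise) {
    cat("pairwise p:\n")
    print(round(m, 6))
  }
  if (length(object@notes)) cat("notes:", paste(object@notes, collapse = "; "), "\n")
})

#' @rdname StatsReport-accessors
#' @param object a [StatsReport-class].
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname StatsReport-accessors
#' @export
setMethod("pValues", "StatsReport", function(object) object@pValues)

#' @rdname StatsReport-accessors
#' @export
setGeneric("pairwisePValues", function(object) standardGeneric("pairwisePValues"))

#' @rdname StatsReport-accessors
#' @export
setMethod("pairwisePValues", "StatsReport", function(object)
  if (length(object@pairwise)) object@pairwise$p else NULL)

#' @rdname StatsReport-accessors
#' @export
setGeneric("reportSummary", function(object) standardGeneric("reportSummary"))

#' @rdname StatsReport-accessors
#' @export
setMethod("reportSummary", "StatsReport", function(object) object@summary)
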