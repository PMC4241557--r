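#' One-way ANOVA with Tukey HSD over developmental stages
#'
#' Fixed-effects one-way ANOVA followed by Tukey's honestly-significant-
#' difference test (Tukey-Kramer for unbalanced groups) giving an adjusted p
#' value for every stage pair. Groups with fewer than 2 non-missing values
#' are dropped with a warning; if all values are identical the degenerate F
#' is handled by returning p = 1 for every pair.
#'
#' @param values numeric vector
#' @param groups group label per value
#' @return data.frame `stage_a`, `stage_b`, `p_adj` (one row per unordered
#'   pair of retained groups)
#' @export
anova_tukey <- function(values, groups) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  cnt <- table(groups)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning(sprintf("dropping groups with < 2 values: %s",
                    paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  g <- factor(groups)
  if (nlevels(g) < 2)
    abort("need at least 2 groups with >= 2 values", "insufficient_data_error")
  pairs <- t(combn(levels(g), 2))
  if (var(values) == 0) {
    return(data.frame(stage_a = pairs[, 1], stage_b = pairs[, 2],
                      p_adj = 1, stringsAsFactors = FALSE))
  }
  # group labels may contain '-' (e.g. stage bins), which would make the
  # TukeyHSD row names unparseable; recode to safe internal levels
  gi <- factor(sprintf("L%02d", as.integer(g)))
  fit <- aov(values ~ gi)
  tk <- TukeyHSD(fit)$gi
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  lv <- function(code) levels(g)[as.integer(sub("L", "", code))]
  data.frame(stage_a = lv(vapply(nm, `[[`, "", 2L)),
             stage_b = lv(vapply(nm, `[[`, "", 1L)),
             p_adj = unname(tk[, "p adj"]), stringsAsFactors = FALSE)
}

#' Code a p value into the four-level significance scale
#'
#' Strict-inequality binning: `p<0.001`, `p<0.01`, `p<0.05`, `ns`.
#'
#' @param p p value(s) in `[0, 1]`
#' @return ordered factor with levels `ns < p<0.05 < p<0.01 < p<0.001`
#' @export
significance_code <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    abort("p values must lie in [0, 1]", "validation_error")
  lab <- ifelse(is.na(p), NA_character_,
                ifelse(p < 0.001, "p<0.001",
                       ifelse(p < 0.01, "p<0.01",
                              ifelse(p < 0.05, "p<0.05", "ns"))))
  factor(lab, levels = c("ns", "p<0.05", "p<0.01", "p<0.001"),
         ordered = TRUE)
}

#' Build the pairwise-stage statistical stacking table
#'
#' For every parameter, a one-way ANOVA with Tukey HSD across stages; every
#' stage pair then gets one significance code per parameter. With all 15
#' stages present this is the 105-cell two-entry table, each cell holding 16
#' parameter sub-cells. Parameters with no measured values in >= 2 stages
#' are marked `not_measured`.
#'
#' @param cohort feature data.frame with a `stage` column
#' @param parameters parameter columns to include
#' @return data.frame of class `stacking_table`: `stage_a`, `stage_b`,
#'   `parameter`, `p_adj`, `code`
#' @export
build_stacking_table <- function(cohort, parameters = feature_names()) {
  stages <- intersect(stage_levels(), unique(cohort$stage))
  if (length(stages) < 2)
    abort("cohort must span at least 2 stages", "insufficient_data_error")
  pairs <- t(combn(stages, 2))
  all_pairs <- data.frame(stage_a = pairs[, 1], stage_b = pairs[, 2],
                          stringsAsFactors = FALSE)
  out <- lapply(parameters, function(p) {
    res <- tryCatch(
      suppressWarnings(anova_tukey(cohort[[p]], cohort$stage)),
      error = function(e) NULL)
    m <- all_pairs
    m$parameter <- p
    if (is.null(res)) {
      m$p_adj <- NA_real_
      m$code <- "not_measured"
    } else {
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      i <- match(key(m$stage_a, m$stage_b), key(res$stage_a, res$stage_b))
      m$p_adj <- res$p_adj[i]
      m$code <- ifelse(is.na(m$p_adj), "not_measured",
                       as.character(significance_code(m$p_adj)))
    }
    m
  })
  tab <- do.call(rbind, out)
  tab <- tab[order(match(tab$stage_a, stage_levels()),
                   match(tab$stage_b, stage_levels()),
                   match(tab$parameter, parameters)), ]
  rownames(tab) <- NULL
  class(tab) <- c("stacking_table", class(tab))
  tab
}

#' Write a stacking table to CSV
#' @param table a `stacking_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stacking_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
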