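#' Group summaries with percent change and one-way ANOVA
#'
#' Aggregates per-sample metric values into the reporting layout used for
#' treatment-group comparisons: per-group n, mean and sample standard
#' deviation (n - 1 denominator), percent change of each group mean versus a
#' reference group, and a one-way ANOVA omnibus F and p per metric.
#'
#' @param data data frame with at least a grouping column and a value
#'   column; an optional metric column yields one summary block per metric.
#' @param value,group,metric column names (metric may be `NULL`).
#' @param reference_group group label used as the percent-change reference;
#'   `NULL` skips percent changes.
#' @return a data frame of class `group_summary`, ordered by (metric,
#'   group), with columns `metric`, `group`, `n`, `mean`, `sd`,
#'   `pct_change_vs_ref`, `anova_F`, `anova_p`.
#' @examples
#' d <- data.frame(group = rep(c("TZB", "TZB+ATV"), each = 4),
#'                 value = c(1.7, 1.75, 1.71, 1.73, 2.7, 2.8, 2.75, 2.78))
#' summarize_groups(d, reference_group = "TZB")
#' @export
summarize_groups <- function(data, value = "value", group = "group",
                             metric = NULL, reference_group = NULL) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  if (!is.null(metric) && !metric %in% names(data))
    stop(sprintf("no column '%s'", metric), call. = FALSE)
  blocks <- if (is.null(metric)) list(`value` = data)
            else split(data, data[[metric]])

  out <- lapply(names(blocks), function(mn) {
    d <- blocks[[mn]]
    g <- factor(d[[group]])
    v <- d[[value]]
    if (nlevels(g) < 2)
      stop("need >= 2 groups for ANOVA", call. = FALSE)
    if (!is.null(reference_group) && !reference_group %in% levels(g))
      stop(sprintf("reference group '%s' missing", reference_group),
           call. = FALSE)
    an <- stats::anova(stats::lm(v ~ g))
    Fv <- an[1, "F value"]; pv <- an[1, "Pr(>F)"]
    if (is.finite(an[1, "Mean Sq"]) && an[2, "Mean Sq"] == 0 &&
        an[1, "Mean Sq"] == 0) { Fv <- 0; pv <- 1 }
    ns <- tapply(v, g, length)
    mus <- tapply(v, g, mean)
    sds <- tapply(v, g, stats::sd)
    if (any(ns == 1))
      warning("group(s) with a single observation: SD undefined")
    ref_mu <- if (is.null(reference_group)) NA_real_
              else mus[[reference_group]]
    pct <- if (is.null(reference_group)) rep(NA_real_, nlevels(g))
           else if (ref_mu <= 0) {
             warning("reference mean not positive: percent change undefined")
             rep(NA_real_, nlevels(g))
           } else percent_change(as.numeric(mus), ref_mu)
    data.frame(metric = mn, group = levels(g), n = as.integer(ns),
               mean = as.numeric(mus), sd = as.numeric(sds),
               pct_change_vs_ref = pct,
               anova_F = Fv, anova_p = pv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$metric, res$group), ]
  rownames(res) <- NULL
  class(res) <- c("group_summary", "data.frame")
  res
}

#' Caliper tumor volume
#'
#' Standard xenograft estimate from two caliper measurements:
#' `width^2 * length * 0.4`.
#'
#' @param width,length_ caliper width and length in millimetres (> 0);
#'   vectorized.
#' @return volume in cubic millimetres.
#' @examples
#' tumor_volume(10, 10)  # 400
#' @export
tumor_volume <- function(width, length_) {
  if (any(width <= 0) || any(length_ <= 0))
    stop("width and length must be positive", call. = FALSE)
  width^2 * length_ * 0.4
}
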