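#' Assemble a neuron-level metric table
#'
#' Long-format container for group comparisons: one row per neuron per
#' metric, with session/animal nesting so mixed-effects comparisons can
#' guard against pseudoreplication.
#'
#' @param value numeric metric values, one per neuron.
#' @param metric metric name.
#' @param group `"control"` or `"knockout"` (recycled).
#' @param animal_id,session_id grouping identifiers (recycled).
#' @param neuron_id optional neuron ids.
#' @return data.frame with class `neuron_metric_table`.
#' @export
neuron_metric_table <- function(value, metric, group, animal_id,
                                session_id = animal_id, neuron_id = NULL) {
  d <- data.frame(neuron_id = neuron_id %||% seq_along(value),
                  session_id = session_id, animal_id = animal_id,
                  group = group, metric = metric, value = value)
  d <- d[is.finite(d$value), ]
  class(d) <- c("neuron_metric_table", "data.frame")
  d
}

#' Mixed-effects group comparison of a neuron-level metric
#'
#' Fits `value ~ group + (1 | animal_id)` and reports the two-tailed
#' t-statistic and p-value of the group fixed effect (Satterthwaite degrees
#' of freedom). Neurons are the observations; the random intercept absorbs
#' animal-level dependence so the test is not pseudoreplicated. With fewer
#' than two animals in a group no random-effect estimate is possible; the
#' function falls back to an ordinary linear model with a warning.
#'
#' @param table a [neuron_metric_table()] (possibly several metrics).
#' @param metric which metric to compare.
#' @param random grouping factor for the random intercept: `"animal_id"`
#'   (default) or `"session_id"`.
#' @return data.frame (metric, estimate, t_stat, df, p_value, n_control,
#'   n_knockout, method).
#' @export
lme_group_compare <- function(table, metric, random = "animal_id") {
  d <- table[table$metric == metric, ]
  if (nrow(d) == 0) stop("no rows for metric ", metric)
  d$group <- factor(d$group)
  n_animals <- tapply(d[[random]], d$group, function(z) length(unique(z)))
  counts <- table(d$group)
  if (any(n_animals < 2)) {
    warning("a group has a single ", random,
            "; falling back to a fixed-effects linear model")
    fit <- stats::lm(value ~ group, data = d)
    s <- summary(fit)$coefficients
    return(data.frame(metric = metric, estimate = s[2, 1], t_stat = s[2, 3],
                      df = fit$df.residual, p_value = s[2, 4],
                      n_control = as.integer(counts[1]),
                      n_knockout = as.integer(counts[2]), method = "lm"))
  }
  f <- as.formula(paste0("value ~ group + (1|", random, ")"))
  fit <- lmerTest::lmer(f, data = d,
                        control = lme4::lmerControl(check.conv.singular =
                          lme4::.makeCC(action = "ignore", tol = 1e-4)))
  s <- summary(fit)$coefficients
  data.frame(metric = metric, estimate = s[2, "Estimate"],
             t_stat = s[2, "t value"], df = s[2, "df"],
             p_value = s[2, "Pr(>|t|)"],
             n_control = as.integer(counts[1]),
             n_knockout = as.integer(counts[2]),
             method = "lme")
}

#' Two-sample distribution tests
#'
#' Standard two-sided two-sample tests used for group comparisons that do
#' not need the nesting structure: Mann-Whitney U, Kolmogorov-Smirnov, or
#' unpaired t-test.
#'
#' @param a,b numeric samples.
#' @param method `"mannwhitney"`, `"ks"` or `"t"`.
#' @return data.frame (method, statistic, p_value, n_a, n_b).
#' @export
distribution_tests <- function(a, b, method = c("mannwhitney", "ks", "t")) {
  method <- match.arg(method)
  stopifnot(length(a) > 0, length(b) > 0)
  res <- switch(method,
    mannwhitney = {
      if (length(unique(c(a, b))) == 1L) {
        warning("all pooled values identical; Mann-Whitney p set to 1")
        list(statistic = length(a) * length(b) / 2, p.value = 1)
      } else {
        suppressWarnings(wilcox.test(a, b, exact = FALSE))
      }
    },
    ks = suppressWarnings(ks.test(a, b)),
    t = t.test(a, b))
  data.frame(method = method, statistic = unname(res$statistic),
             p_value = res$p.value, n_a = length(a), n_b = length(b))
}
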