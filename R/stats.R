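#' Load the embedded 27-patient crossover enhancement table
#'
#' Per-patient net QE and per-ROI average QE for gadoteridol and gadobutrol
#' in 27 glioblastoma patients who received both agents at 0.1 mmol/kg in
#' two otherwise identical examinations. The agent order of each examination
#' was randomised; it is recorded (`first_agent`) only for the two patients
#' whose worked examples publish it, and is `NA` elsewhere. On load, every
#' difference column is recomputed from its two value columns and checked
#' against the stored differences (within 0.1 for net QE, 0.001 for average
#' QE, i.e. last-digit rounding of the stored values); any discrepancy stops
#' with a fixture-integrity error.
#'
#' @param path CSV path; defaults to the copy installed with the package.
#' @return A data frame of 27 patient records with columns `patient`,
#'   `net_gadoteridol`, `net_gadobutrol`, `net_difference`,
#'   `avg_gadoteridol`, `avg_gadobutrol`, `avg_difference`, `first_agent`.
#' @export
load_table1 <- function(path = system.file("extdata", "table1_net_avg_qe.csv",
                                           package = "qea")) {
  if (!nzchar(path) || !file.exists(path)) stop("fixture not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "NA")
  need <- c("patient", "net_gadoteridol", "net_gadobutrol", "net_difference",
            "avg_gadoteridol", "avg_gadobutrol", "avg_difference",
            "first_agent")
  if (!all(need %in% names(tab)))
    stop("fixture integrity: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (nrow(tab) != 27L)
    stop("fixture integrity: expected 27 patient records, found ", nrow(tab))
  if (!identical(tab$patient, 1:27))
    stop("fixture integrity: patient ids are not 1..27")
  dn <- tab$net_gadoteridol - tab$net_gadobutrol
  da <- tab$avg_gadoteridol - tab$avg_gadobutrol
  if (max(abs(dn - tab$net_difference)) > 0.1 + 1e-9)
    stop("fixture integrity: a net QE difference disagrees with its columns ",
         "by more than 0.1")
  if (max(abs(da - tab$avg_difference)) > 0.001 + 1e-9)
    stop("fixture integrity: an average QE difference disagrees with its ",
         "columns by more than 0.001")
  if (any(tab$avg_gadoteridol < 0 | tab$avg_gadoteridol > 1 |
            tab$avg_gadobutrol < 0 | tab$avg_gadobutrol > 1))
    stop("fixture integrity: average QE outside [0, 1]")
  tab
}

#' Paired t-test on a vector of paired differences
#'
#' Two-sided one-sample t-test of the differences against zero, with the
#' 95% confidence interval for the mean difference. Degenerate inputs
#' follow the limiting conventions: all-zero differences give `p = 1`
#' (no signal), zero variance with a nonzero mean gives `p = 0`.
#'
#' @param diffs numeric vector of paired differences, length `>= 2`.
#' @return An object of class `paired_t_result` with fields `n`,
#'   `mean_diff`, `sd_diff`, `ci95`, `t`, `p`.
#' @export
paired_t <- function(diffs) {
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 2L) stop("paired t-test needs at least 2 differences")
  if (any(!is.finite(diffs))) stop("differences must be finite")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    ci <- c(m, m)
  } else {
    se <- s / sqrt(n)
    t_stat <- m / se
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
    half <- stats::qt(0.975, df = n - 1) * se
    ci <- c(m - half, m + half)
  }
  structure(list(n = n, mean_diff = m, sd_diff = s, ci95 = ci,
                 t = t_stat, p = p),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat("<paired_t> n = ", x$n, ", mean diff ", signif(x$mean_diff, 4), " +/- ",
      signif(x$sd_diff, 4), ", t = ", signif(x$t, 4), ", p = ",
      signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper over [stats::cor()]: requires equal lengths
#' `>= 3` and nonzero variance in both arguments.
#'
#' @param x,y numeric vectors.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return The rank correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 pairs")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("zero rank variance: correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' Bland-Altman agreement analysis
#'
#' Per-pair means `(x + y) / 2` and differences `x - y`, the mean
#' difference (fixed bias) and limits of agreement defined as the mean
#' difference plus/minus exactly 2 standard deviations of the differences.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return An object of class `bland_altman_result` with fields `means`,
#'   `diffs`, `mean_diff`, `sd_diff`, `limits` (length-2 lower/upper).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("Bland-Altman needs at least 2 pairs")
  diffs <- x - y
  m <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(means = (x + y) / 2, diffs = diffs,
                 mean_diff = m, sd_diff = s,
                 limits = c(m - 2 * s, m + 2 * s)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat("<bland_altman> mean diff ", signif(x$mean_diff, 4),
      ", limits of agreement [", signif(x$limits[1], 4), ", ",
      signif(x$limits[2], 4), "]\n", sep = "")
  invisible(x)
}

#' Count which agent enhanced more, patient by patient
#'
#' @param diffs numeric vector of paired differences (positive favours
#'   `positive_label`).
#' @param positive_label,negative_label agent names for the two signs.
#' @return A data frame with one row per category (`positive`, `negative`,
#'   `zero`) carrying the label, count and percentage of `n`.
#' @export
preference_counts <- function(diffs, positive_label = "gadoteridol",
                              negative_label = "gadobutrol") {
  if (length(diffs) < 1L) stop("need at least one difference")
  n <- length(diffs)
  counts <- c(positive = sum(diffs > 0), negative = sum(diffs < 0),
              zero = sum(diffs == 0))
  data.frame(category = names(counts),
             label = c(positive_label, negative_label, "equal"),
             count = as.integer(counts),
             percent = 100 * as.numeric(counts) / n,
             row.names = NULL)
}

#' Percent difference between the two examinations' net QE
#'
#' The signed gadoteridol-minus-gadobutrol net QE difference expressed as a
#' percentage of the first examination's net QE (the first exam is the
#' natural reference: it precedes any carryover or lesion evolution).
#'
#' @param net_first_exam,net_second_exam net QE of the two examinations in
#'   temporal order.
#' @param first_agent which agent the first examination used.
#' @return List with `difference` (gadoteridol minus gadobutrol),
#'   `percent` (signed, of the first exam) and `percent_abs`.
#' @export
percent_difference <- function(net_first_exam, net_second_exam,
                               first_agent = c("gadoteridol", "gadobutrol")) {
  first_agent <- match.arg(first_agent)
  if (net_first_exam == 0) stop("first-examination net QE is zero")
  diff <- if (first_agent == "gadoteridol")
    net_first_exam - net_second_exam else net_second_exam - net_first_exam
  pct <- 100 * diff / net_first_exam
  list(difference = diff, percent = pct, percent_abs = abs(pct))
}

#' Full between-agent statistical battery on per-patient records
#'
#' Runs every cohort-level comparison on a table of per-patient net and
#' average QE values: paired t-tests on the net and average differences,
#' Pearson correlations between the agents' columns, Bland-Altman
#' agreement on the average QE, and the per-patient preference counts.
#'
#' @param records a data frame in the [load_table1()] layout (the
#'   difference columns are optional and recomputed), with columns
#'   `net_<agent>` and `avg_<agent>` for both agents.
#' @param agents length-2 character: the two agent labels, in the order
#'   differences are taken (`agents[1]` minus `agents[2]`).
#' @return A list of results keyed `net_t`, `avg_t`, `net_pearson`,
#'   `avg_pearson`, `avg_bland_altman`, `net_bland_altman`, `preference`,
#'   plus `n` and `agents`.
#' @export
agent_stats_report <- function(records,
                               agents = c("gadoteridol", "gadobutrol")) {
  stopifnot(length(agents) == 2L)
  need <- c(paste0("net_", agents), paste0("avg_", agents))
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  n1 <- records[[paste0("net_", agents[1])]]
  n2 <- records[[paste0("net_", agents[2])]]
  a1 <- records[[paste0("avg_", agents[1])]]
  a2 <- records[[paste0("avg_", agents[2])]]
  # correlations need at least 3 pairs; a 2-patient cohort still gets the
  # paired tests and agreement analysis
  cor_or_na <- function(x, y) if (length(x) >= 3L) pearson_r(x, y) else NA_real_
  list(n = nrow(records), agents = agents,
       net_t = paired_t(n1 - n2),
       avg_t = paired_t(a1 - a2),
       net_pearson = cor_or_na(n1, n2),
       avg_pearson = cor_or_na(a1, a2),
       net_bland_altman = bland_altman(n1, n2),
       avg_bland_altman = bland_altman(a1, a2),
       preference = preference_counts(a1 - a2, positive_label = agents[1],
                                      negative_label = agents[2]))
}
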