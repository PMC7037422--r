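#' Relative quantification by the 2^-ddCt method
#'
#' Classic comparative-Ct fold change with amplification efficiency fixed
#' at 2 (perfect doubling per cycle):
#' \deqn{\Delta\Delta Ct = (Ct_{target} - Ct_{ref}) -
#'       (Ct_{target}^{ctrl} - Ct_{ref}^{ctrl}), \qquad
#'       fold = 2^{-\Delta\Delta Ct}.}
#' Vector inputs are averaged first (technical replicates).
#'
#' @param target_ct,ref_ct Ct of the target and reference gene in the
#'   condition of interest.
#' @param target_ct_ctrl,ref_ct_ctrl same in the normalizer condition
#'   (untreated, non-irradiated control of the same timepoint).
#' @return the fold change (> 0).
#' @export
#' @examples
#' delta_delta_ct(24, 18, 26, 18)   # -> 4
delta_delta_ct <- function(target_ct, ref_ct, target_ct_ctrl, ref_ct_ctrl) {
  vals <- c(target_ct, ref_ct, target_ct_ctrl, ref_ct_ctrl)
  if (any(!is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (mean(target_ct) - mean(ref_ct)) -
    (mean(target_ct_ctrl) - mean(ref_ct_ctrl))
  2^(-ddct)
}

#' Fold-change table from a tidy Ct table
#'
#' Computes 2^-ddCt per gene and condition against the untreated
#' non-irradiated control of the same timepoint, normalized by the named
#' reference gene. The normalizer condition's fold change is 1 by
#' construction.
#'
#' @param ct_table data frame with columns `gene`, `nm_type`,
#'   `dose_surface`, `irradiated`, `timepoint_h`, `replicate`, `ct` (as
#'   emitted by [simulate_pcr()]).
#' @param reference_gene the housekeeping gene used as normalizer.
#' @return data frame of `gene`, condition fields and `fold_change`.
#' @export
fold_change_table <- function(ct_table, reference_gene = "GAPDH") {
  need <- c("gene", "nm_type", "dose_surface", "irradiated",
            "timepoint_h", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must contain columns ", paste(need, collapse = ", "))
  if (!(reference_gene %in% ct_table$gene))
    stop("reference gene ", reference_gene, " absent from the table")
  mean_ct <- aggregate(
    ct ~ gene + nm_type + dose_surface + irradiated + timepoint_h,
    data = ct_table, FUN = mean)
  out <- do.call(rbind, lapply(split(mean_ct, mean_ct$timepoint_h), function(tp) {
    ctrl <- tp[tp$dose_surface == 0 & !tp$irradiated, ]
    if (nrow(ctrl) == 0)
      stop("no untreated non-irradiated control at timepoint ",
           tp$timepoint_h[1])
    ref_ctrl <- ctrl$ct[ctrl$gene == reference_gene]
    targets <- tp[tp$gene != reference_gene, ]
    targets$fold_change <- vapply(seq_len(nrow(targets)), function(i) {
      g <- targets$gene[i]
      ref_here <- tp$ct[tp$gene == reference_gene &
                          tp$nm_type == targets$nm_type[i] &
                          tp$dose_surface == targets$dose_surface[i] &
                          tp$irradiated == targets$irradiated[i]]
      if (length(ref_here) == 0)
        stop("missing reference-gene record for a condition")
      tgt_ctrl <- ctrl$ct[ctrl$gene == g]
      delta_delta_ct(targets$ct[i], ref_here, tgt_ctrl, ref_ctrl)
    }, numeric(1))
    targets
  }))
  rownames(out) <- NULL
  out$ct <- NULL
  out
}

#' Welch two-sample t-test
#'
#' Two-sided t-test without the equal-variance assumption, with
#' Welch-Satterthwaite degrees of freedom (the comparison used for all
#' cell-death contrasts). Thin wrapper over [stats::t.test()] that
#' enforces the preconditions (two or more values per group, nonzero
#' variance) and returns a flat result.
#'
#' @param group_a,group_b numeric vectors (each length >= 2 with nonzero
#'   variance).
#' @return list: `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4.1, 5.2, 5.9))
welch_t <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (length(g) < 2 || any(!is.finite(g)))
      stop("each group needs >= 2 finite values")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stop("degenerate input: both groups have zero variance")
  res <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

p_stars <- function(p, symbol = "*") {
  ifelse(p < 0.001, strrep(symbol, 3),
         ifelse(p < 0.01, strrep(symbol, 2),
                ifelse(p < 0.05, symbol, "")))
}

#' Standard comparison families for a mortality table
#'
#' Runs the two Welch t-test families used for the cell-death data:
#' * `IR_vs_NI` — each irradiated condition against the matching
#'   non-irradiated condition (same nanomaterial, dose, timepoint);
#'   significance marked with `*`.
#' * `dose_vs_IRctrl` — each nanomaterial dose on irradiated cells
#'   against the irradiated untreated control of the same timepoint;
#'   marked with `#`.
#'
#' Conditions with fewer than two replicates in either group are skipped
#' with a warning. No multiple-testing correction is applied by default
#' (set `adjust = "BH"` for Benjamini-Hochberg within each family).
#'
#' @param death_table data frame with columns `nm_type`, `dose_surface`,
#'   `irradiated`, `timepoint_h`, `replicate`, `mortality`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame: `family`, `nm_type`, `dose_surface`,
#'   `timepoint_h`, `t`, `df`, `p`, `stars`.
#' @export
comparison_suite <- function(death_table, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- c("nm_type", "dose_surface", "irradiated", "timepoint_h",
            "replicate", "mortality")
  if (!all(need %in% names(death_table)))
    stop("death_table must contain columns ", paste(need, collapse = ", "))
  dt <- death_table
  rows <- list()
  skipped <- 0L

  grp <- function(nm, dose, ir, tp)
    dt$mortality[dt$nm_type == nm & dt$dose_surface == dose &
                   dt$irradiated == ir & dt$timepoint_h == tp]

  combos <- unique(dt[dt$irradiated, c("nm_type", "dose_surface", "timepoint_h")])
  for (i in seq_len(nrow(combos))) {
    nm <- combos$nm_type[i]; dose <- combos$dose_surface[i]
    tp <- combos$timepoint_h[i]
    a <- grp(nm, dose, TRUE, tp); b <- grp(nm, dose, FALSE, tp)
    if (length(a) >= 2 && length(b) >= 2 && (sd(a) > 0 || sd(b) > 0)) {
      w <- welch_t(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        family = "IR_vs_NI", nm_type = nm, dose_surface = dose,
        timepoint_h = tp, t = w$t, df = w$df, p = w$p)
    } else skipped <- skipped + 1L
    # second family: NM dose on irradiated cells vs irradiated control
    if (dose > 0) {
      ctrl <- dt$mortality[dt$dose_surface == 0 & dt$irradiated &
                             dt$timepoint_h == tp]
      if (length(a) >= 2 && length(ctrl) >= 2 && (sd(a) > 0 || sd(ctrl) > 0)) {
        w <- welch_t(a, ctrl)
        rows[[length(rows) + 1L]] <- data.frame(
          family = "dose_vs_IRctrl", nm_type = nm, dose_surface = dose,
          timepoint_h = tp, t = w$t, df = w$df, p = w$p)
      } else skipped <- skipped + 1L
    }
  }
  if (skipped > 0)
    warning(skipped, " comparison(s) skipped for missing replicates or zero variance")
  if (length(rows) == 0)
    return(data.frame(family = character(), nm_type = character(),
                      dose_surface = numeric(), timepoint_h = numeric(),
                      t = numeric(), df = numeric(), p = numeric(),
                      stars = character()))
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    for (f in unique(out$family))
      out$p[out$family == f] <- stats::p.adjust(out$p[out$family == f], "BH")
  }
  out$stars <- ifelse(out$family == "IR_vs_NI",
                      p_stars(out$p, "*"), p_stars(out$p, "#"))
  rownames(out) <- NULL
  out
}
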