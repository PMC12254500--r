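#' Read a qPCR Ct table from CSV
#'
#' Expected columns: sample, group (experimental|control), fraction
#' (RIP|input), target, ct, dilution_factor (for input rows; may be empty
#' elsewhere). Tables for plain relative-expression analysis may omit
#' `fraction` and `dilution_factor`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group", "target", "ct") %in% names(tab)))
  tab
}

.mean_ct <- function(table, group, fraction, target) {
  rows <- table[table$group == group & table$fraction == fraction &
                  table$target == target, , drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("no Ct values for (group=%s, fraction=%s, target=%s)",
                 group, fraction, target))
  if (any(!is.finite(rows$ct)))
    stop(sprintf("non-finite Ct in (group=%s, fraction=%s, target=%s)",
                 group, fraction, target))
  rows
}

#' RIP-qPCR fold enrichment
#'
#' Per target and group the RIP signal is normalized to the diluted input:
#' delta-Ct = Ct(RIP) - [Ct(input) - log2(input dilution factor)], with
#' technical replicates averaged (arithmetic mean of Ct) before the
#' subtraction. The between-group difference gives
#' delta-delta-Ct = dCt(experimental) - dCt(control) and the fold
#' enrichment 2^(-ddCt); the control group is 1 by construction. The fold
#' is finally adjusted for immunoprecipitation efficiency by the ratio of
#' precipitated bait-protein levels,
#' ip_protein_ratio = IP(experimental) / IP(control): by default the fold
#' is divided by this ratio, so that more efficiently precipitated protein
#' does not inflate the apparent RNA enrichment (`direction = "multiply"`
#' selects the reciprocal reading).
#'
#' @param table Ct data.frame with columns sample, group, fraction, target,
#'   ct, dilution_factor.
#' @param ip_protein_ratio positive real; default 1 (no adjustment).
#' @param direction `"divide"` (default) or `"multiply"` the fold by the
#'   IP-protein ratio.
#' @param experimental,control the group labels.
#' @return data.frame of class `rip_result`, one row per target:
#'   dct_experimental, dct_control, ddct, fold_enrichment, adjusted_fold,
#'   control_fold (1 by construction).
#' @export
rip_fold_enrichment <- function(table, ip_protein_ratio = 1,
                                direction = c("divide", "multiply"),
                                experimental = "experimental",
                                control = "control") {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(table), ip_protein_ratio > 0)
  needed <- c("group", "fraction", "target", "ct", "dilution_factor")
  stopifnot(all(needed %in% names(table)))
  targets <- unique(table$target)
  dct_group <- function(group, target) {
    rip <- .mean_ct(table, group, "RIP", target)
    inp <- .mean_ct(table, group, "input", target)
    dil <- unique(inp$dilution_factor)
    if (length(dil) != 1L || is.na(dil))
      stop(sprintf("input dilution factor not unique for (group=%s, target=%s)",
                   group, target))
    if (dil <= 0)
      stop(sprintf("nonpositive input dilution factor for (group=%s, target=%s)",
                   group, target))
    mean(rip$ct) - (mean(inp$ct) - log2(dil))
  }
  rows <- lapply(targets, function(tg) {
    dct_exp <- dct_group(experimental, tg)
    dct_ctrl <- dct_group(control, tg)
    ddct <- dct_exp - dct_ctrl
    fold <- 2^(-ddct)
    adj <- if (direction == "divide") fold / ip_protein_ratio
           else fold * ip_protein_ratio
    data.frame(target = tg,
               dct_experimental = dct_exp, dct_control = dct_ctrl,
               ddct = ddct, fold_enrichment = fold,
               adjusted_fold = adj, control_fold = 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("rip_result", class(res))
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, delta-Ct = Ct(target) - Ct(reference); delta-delta-Ct is
#' taken against the mean delta-Ct of the control group, and relative
#' expression is 2^(-ddCt). The control group's geometric mean is 1 by
#' construction. Adding a constant to every Ct leaves the result unchanged.
#'
#' @param table Ct data.frame with columns sample, group, target, ct.
#' @param reference_target the reference gene present in every sample.
#' @param control the control group label.
#' @return data.frame, one row per (sample, non-reference target):
#'   dct, ddct, rel_expression.
#' @export
ddct_expression <- function(table, reference_target, control = "control") {
  stopifnot(is.data.frame(table),
            all(c("sample", "group", "target", "ct") %in% names(table)))
  if (!reference_target %in% table$target)
    stop("reference target not present: ", reference_target)
  samples <- unique(table$sample)
  targets <- setdiff(unique(table$target), reference_target)
  rows <- list()
  for (tg in targets) {
    per_sample <- lapply(samples, function(sm) {
      sub <- table[table$sample == sm, , drop = FALSE]
      tg_ct <- sub$ct[sub$target == tg]
      ref_ct <- sub$ct[sub$target == reference_target]
      if (!length(ref_ct))
        stop("sample without reference target: ", sm)
      if (!length(tg_ct)) return(NULL)
      data.frame(sample = sm, group = unique(sub$group)[1], target = tg,
                 dct = mean(tg_ct) - mean(ref_ct),
                 stringsAsFactors = FALSE)
    })
    per_sample <- do.call(rbind, per_sample)
    ctrl_mean <- mean(per_sample$dct[per_sample$group == control])
    if (is.nan(ctrl_mean))
      stop("no control-group samples for target: ", tg)
    per_sample$ddct <- per_sample$dct - ctrl_mean
    per_sample$rel_expression <- 2^(-per_sample$ddct)
    rows[[tg]] <- per_sample
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Relative retrotransposition activity from colony counts
#'
#' Activity = colonies(reporter-transfected) / colonies(empty-vector
#' control), per condition, which controls for toxicity of the
#' co-expressed construct. Optionally renormalized so a designated
#' reference condition equals 1.
#'
#' @param counts data.frame with columns condition, colonies_l1neo,
#'   colonies_control (nonnegative integers).
#' @param normalize_to optional condition label set to 1.
#' @return data.frame with condition, activity and (when requested)
#'   relative_activity.
#' @export
retro_activity <- function(counts, normalize_to = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("condition", "colonies_l1neo", "colonies_control") %in%
                  names(counts)))
  l1 <- counts$colonies_l1neo; ctrl <- counts$colonies_control
  if (any(l1 < 0) || any(ctrl < 0) ||
      any(l1 != round(l1)) || any(ctrl != round(ctrl)))
    stop("colony counts must be nonnegative integers")
  if (any(ctrl == 0))
    stop("zero control colonies for condition: ",
         paste(counts$condition[ctrl == 0], collapse = ", "))
  res <- data.frame(condition = counts$condition,
                    activity = l1 / ctrl,
                    stringsAsFactors = FALSE)
  if (!is.null(normalize_to)) {
    ref <- res$activity[res$condition == normalize_to]
    if (length(ref) != 1L)
      stop("normalization condition not found (or duplicated): ",
           normalize_to)
    res$relative_activity <- res$activity / ref
  }
  res
}

#' Read a colony-count table from CSV
#'
#' Long format with columns condition, plasmid, colonies; the two plasmid
#' labels identify the retrotransposition reporter and the empty-vector
#' control.
#'
#' @param path CSV file.
#' @param l1_plasmid,control_plasmid the plasmid labels.
#' @return wide data.frame suitable for [retro_activity()].
#' @export
read_colony_counts <- function(path, l1_plasmid = "L1-neo",
                               control_plasmid = "pcDNA3.1") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "plasmid", "colonies") %in% names(tab)))
  conditions <- unique(tab$condition)
  pick <- function(cond, plasmid) {
    v <- tab$colonies[tab$condition == cond & tab$plasmid == plasmid]
    if (length(v) != 1L)
      stop(sprintf("expected exactly one '%s' count for condition '%s'",
                   plasmid, cond))
    v
  }
  data.frame(condition = conditions,
             colonies_l1neo = vapply(conditions, pick, numeric(1),
                                     plasmid = l1_plasmid),
             colonies_control = vapply(conditions, pick, numeric(1),
                                       plasmid = control_plasmid),
             stringsAsFactors = FALSE)
}
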