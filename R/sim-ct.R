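#' Simulate a RIP-qPCR Ct table with a known true fold enrichment
#'
#' Constructs Ct values whose RIP enrichment, computed with
#' [rip_fold_enrichment()], equals `true_fold` exactly when `noise_sd` is
#' zero (the generator is the exact inverse of the enrichment formulas);
#' with `noise_sd > 0` independent Gaussian noise of that standard
#' deviation is added to every Ct value.
#'
#' @param true_fold the planted fold enrichment (> 0).
#' @param dilution_factor input dilution factor (> 0), e.g. 10 for a 1:10
#'   input.
#' @param noise_sd Ct noise standard deviation (>= 0, cycles).
#' @param n_replicates technical replicates per (group, fraction) cell.
#' @param seed integer seed.
#' @param target target label written into the table.
#' @param base_ct baseline input Ct (cycles); cancels in the enrichment.
#' @return Ct data.frame with columns sample, group, fraction, target, ct,
#'   dilution_factor (NA on RIP rows).
#' @export
simulate_ct_table <- function(true_fold, dilution_factor = 10,
                              noise_sd = 0, n_replicates = 3L,
                              seed = 1L, target = "L1_5UTR",
                              base_ct = 20) {
  stopifnot(true_fold > 0, dilution_factor > 0, noise_sd >= 0,
            n_replicates >= 1, n_replicates == round(n_replicates))
  set.seed(seed)
  rip_ctrl <- base_ct + 5
  rip_exp <- rip_ctrl - log2(true_fold)
  grid <- expand.grid(rep = seq_len(n_replicates),
                      fraction = c("RIP", "input"),
                      group = c("experimental", "control"),
                      stringsAsFactors = FALSE)
  clean_ct <- ifelse(grid$fraction == "input", base_ct,
                     ifelse(grid$group == "experimental", rip_exp, rip_ctrl))
  ct <- clean_ct + if (noise_sd > 0)
    stats::rnorm(nrow(grid), sd = noise_sd) else 0
  data.frame(sample = sprintf("%s_%s_%d", grid$group, grid$fraction,
                              grid$rep),
             group = grid$group,
             fraction = grid$fraction,
             target = target,
             ct = ct,
             dilution_factor = ifelse(grid$fraction == "input",
                                      dilution_factor, NA_real_),
             stringsAsFactors = FALSE)
}
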