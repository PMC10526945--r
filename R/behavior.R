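#' Composite aggressive score (CAS)
#'
#' The CAS summarizes 72 h post-mixing aggression as the number of active
#' attacks plus 0.07 times their total duration in seconds, so one second
#' of fighting weighs 7% of one attack event.
#'
#' @param attack_count Non-negative number of active attacks.
#' @param attack_duration_s Non-negative total active-attack duration in
#'   seconds. Recycled against `attack_count`.
#' @return Numeric vector of CAS values, `attack_count + 0.07 *
#'   attack_duration_s`.
#' @examples
#' composite_aggressive_score(12, 60) # 16.2
#' @export
composite_aggressive_score <- function(attack_count, attack_duration_s) {
  if (any(is.na(attack_count)) || any(attack_count < 0))
    stop_bad("attack_count must be non-negative")
  if (any(is.na(attack_duration_s)) || any(attack_duration_s < 0))
    stop_bad("attack_duration_s must be non-negative")
  attack_count + 0.07 * attack_duration_s
}

#' Select extreme phenotype groups by CAS
#'
#' Labels the `n_top` highest-CAS pigs MAP (most aggressive) and the
#' `n_bottom` lowest LAP (least aggressive); everyone else is
#' "unselected". Ties are broken deterministically by (CAS, then pig_id
#' lexicographic), so the selection is invariant to input row order.
#' A median split (the two-step validation variant) is `n_top =
#' ceiling(n/2)`, `n_bottom = floor(n/2)`.
#'
#' @param cas_table data.frame with columns `pig_id` and `cas` (extra
#'   columns are preserved).
#' @param n_top,n_bottom Group sizes; their sum must not exceed the number
#'   of pigs.
#' @return The input with a `group` factor column (levels MAP, LAP,
#'   unselected), rows in the original order.
#' @export
select_extreme_groups <- function(cas_table, n_top, n_bottom) {
  if (!all(c("pig_id", "cas") %in% names(cas_table)))
    stop_bad("cas_table needs columns pig_id and cas")
  n <- nrow(cas_table)
  if (n_top < 0 || n_bottom < 0 || n_top + n_bottom > n)
    stop_bad("n_top + n_bottom (%d) exceeds number of pigs (%d)",
             n_top + n_bottom, n)
  id <- as.character(cas_table$pig_id)
  # descending CAS, ascending pig_id: the documented tie rule
  ord <- order(-cas_table$cas, id)
  group <- rep("unselected", n)
  if (n_top > 0) group[ord[seq_len(n_top)]] <- "MAP"
  if (n_bottom > 0) group[ord[seq.int(n - n_bottom + 1L, n)]] <- "LAP"
  cas_table$group <- factor(group, levels = c("MAP", "LAP", "unselected"))
  cas_table
}
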