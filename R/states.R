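#' Health states of the Crohn's disease model
#'
#' The model is structured around five health states. Three are graded by
#' Crohn's Disease Activity Index (CDAI) score: remission (CDAI < 150),
#' mild disease (150 <= CDAI < 220) and moderate-to-severe disease
#' (220 <= CDAI < 600). The two remaining states are surgery (a transient
#' procedural state with one-cycle residence) and death (absorbing).
#'
#' @param which `"cdai"` for the three disease-activity states only,
#'   `"all"` for the full five-state set.
#' @return Character vector of state labels, in model order.
#' @export
#' @examples
#' health_states()
#' health_states("cdai")
health_states <- function(which = c("all", "cdai")) {
  which <- match.arg(which)
  cdai <- c("remission", "mild", "moderate_severe")
  if (which == "cdai") cdai else c(cdai, "surgery", "death")
}

#' Treatment-status strata of the maintenance state space
#'
#' During maintenance each CDAI state is stratified by treatment status:
#' on biologic at the standard dose, on biologic at the escalated dose,
#' post-biologic (stopped at the end of the treatment duration, efficacy
#' converging to standard of care) and on non-biologic standard of care.
#'
#' @return Character vector of status labels.
#' @export
treatment_statuses <- function() {
  c("bio_std", "bio_esc", "post_bio", "soc")
}

#' Enumerate the expanded maintenance state space
#'
#' CDAI state crossed with treatment status, plus the surgery and death
#' states. Occupancy vectors over this space sum to one every cycle.
#'
#' @return Data frame with columns `state` (label used in traces),
#'   `cdai` and `status` (`NA` for surgery and death).
#' @export
expanded_states <- function() {
  cdai <- health_states("cdai")
  status <- treatment_statuses()
  grid <- expand.grid(cdai = cdai, status = status,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # ordered status-major so each status block is contiguous
  grid <- grid[order(match(grid$status, status), match(grid$cdai, cdai)), ]
  out <- rbind(
    data.frame(state = paste(grid$cdai, grid$status, sep = "."),
               cdai = grid$cdai, status = grid$status,
               stringsAsFactors = FALSE),
    data.frame(state = c("surgery", "death"),
               cdai = NA_character_, status = NA_character_,
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

# index helper: positions of the 3 CDAI states for one status block
.status_block <- function(status) {
  es <- expanded_states()
  which(!is.na(es$status) & es$status == status)
}

.state_index <- function(label) {
  match(label, expanded_states()$state)
}
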