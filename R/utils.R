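# Internal indexing helpers for modified Rankin Scale (mRS) keyed tables.
# Utilities, follow-up costs and hazard ratios are reported with mRS 0 and 1
# merged into a single level, so vectors have 6 (mRS 0-1, 2, 3, 4, 5, 6) or
# 5 (mRS 0-1 .. 5, state 6 absorbing) entries.

mrs_cost_index <- function(mrs) {
  ifelse(mrs <= 1L, 1L, as.integer(mrs))
}

mrs_hr_index <- function(mrs) {
  stopifnot(all(mrs >= 0L & mrs <= 5L))
  ifelse(mrs <= 1L, 1L, as.integer(mrs))
}

mrs_levels <- c("mrs01", "mrs2", "mrs3", "mrs4", "mrs5", "mrs6")

occlusion_sites <- c("ICA", "M1", "M2")

`%||%` <- function(a, b) if (is.null(a)) b else a
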