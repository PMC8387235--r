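# Internal helpers shared across modules.

# Number of spikes (sorted vector) falling in each half-open window [start, end).
count_in_windows <- function(spikes, starts, ends) {
  stopifnot(length(starts) == length(ends))
  if (length(spikes) == 0L) return(rep(0L, length(starts)))
  # findInterval(x, v, left.open = TRUE) = #{v < x}, so the difference counts
  # spikes with start <= t < end.
  findInterval(ends, spikes, left.open = TRUE) -
    findInterval(starts, spikes, left.open = TRUE)
}

# As above, but windows wrap circularly on [0, t_total): `starts` is reduced
# modulo t_total and a window running past the end continues from 0.
count_in_windows_wrapped <- function(spikes, starts, durs, t_total) {
  s <- starts %% t_total
  e <- s + durs
  over <- e > t_total
  cnt <- count_in_windows(spikes, s, pmin(e, t_total))
  if (any(over)) {
    cnt[over] <- cnt[over] +
      count_in_windows(spikes, rep(0, sum(over)), e[over] - t_total)
  }
  cnt
}

assert_sorted_times <- function(t, what = "spike times") {
  if (any(is.na(t))) abort(sprintf("%s contain NA", what))
  if (any(t < 0)) abort(sprintf("%s must be non-negative", what))
  if (is.unsorted(t, strictly = FALSE)) abort(sprintf("%s must be sorted", what))
  invisible(t)
}

# Split a tibble of spikes (unit_id, t_s) into a named list of sorted vectors.
split_spikes <- function(spikes) {
  stopifnot(all(c("unit_id", "t_s") %in% names(spikes)))
  sp <- split(spikes$t_s, spikes$unit_id)
  lapply(sp, function(x) sort(x))
}

behaviour_vocabulary <- function() {
  c("nest_entry", "nest_exit", "chase", "shepherding", "dam_retrieval",
    "pup_drop", "pup_call_bout", "pup_call", "virgin_retrieval", "other")
}
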