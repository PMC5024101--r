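#' Per-stage accounting for the discovery filter cascade
#'
#' A filter ledger records, for every stage of the lincRNA discovery cascade,
#' how many transcripts entered, how many were removed (and why), and how many
#' were retained. It is the single source of truth for cascade counts.
#'
#' @param stages Tibble with columns `stage`, `input_count`, `removed_count`,
#'   `retained_count` (may be empty).
#' @param removed Tibble with columns `stage`, `transcript_id`, `reason`.
#' @return An object of class `filter_ledger`.
#' @export
filter_ledger <- function(stages = NULL, removed = NULL) {
  stages <- stages %||% tibble(stage = character(), input_count = integer(),
                               removed_count = integer(),
                               retained_count = integer())
  removed <- removed %||% tibble(stage = character(),
                                 transcript_id = character(),
                                 reason = character())
  structure(list(stages = as_tibble(stages), removed = as_tibble(removed)),
            class = "filter_ledger")
}

# append one stage; removed_ids may be empty
.ledger_add <- function(ledger, stage, input_ids, removed_ids, reason) {
  n_in <- length(input_ids)
  n_rm <- length(removed_ids)
  ledger$stages <- bind_rows(ledger$stages, tibble(
    stage = stage, input_count = n_in, removed_count = n_rm,
    retained_count = n_in - n_rm
  ))
  if (n_rm) {
    ledger$removed <- bind_rows(ledger$removed, tibble(
      stage = stage, transcript_id = removed_ids, reason = reason
    ))
  }
  ledger
}

#' Check the conservation invariants of a filter ledger
#'
#' Every stage must satisfy `input = removed + retained`, and each stage's
#' input must equal the previous stage's retained count.
#'
#' @param ledger A [filter_ledger()].
#' @return The ledger, invisibly; errors if an invariant is violated.
#' @export
validate_ledger <- function(ledger) {
  s <- ledger$stages
  .assert(all(s$input_count == s$removed_count + s$retained_count),
          "ledger stage with input != removed + retained")
  if (nrow(s) > 1) {
    .assert(all(s$input_count[-1] == s$retained_count[-nrow(s)]),
            "ledger stage input does not chain from previous retained")
  }
  invisible(ledger)
}

#' Chain removal counts through a filter cascade
#'
#' Given the number of transcripts entering a cascade and the number removed at
#' each successive stage, returns the retained count after each stage. This is
#' the arithmetic backbone of the discovery ledger and reproduces published
#' cascade tallies from their per-stage removals.
#'
#' @param input_count Count entering the first stage.
#' @param removed Integer vector of per-stage removal counts, in order.
#' @param stages Optional stage names.
#' @return Tibble: `stage`, `input_count`, `removed_count`, `retained_count`.
#' @examples
#' cascade_counts(3707, c(633, 23), c("protein", "domain"))
#' @export
cascade_counts <- function(input_count, removed, stages = NULL) {
  .assert(length(removed) >= 1, "need at least one stage")
  .assert(all(removed >= 0), "removal counts must be nonnegative")
  stages <- stages %||% paste0("stage_", seq_along(removed))
  inputs <- input_count - cumsum(c(0, removed[-length(removed)]))
  out <- tibble(stage = stages, input_count = as.integer(inputs),
                removed_count = as.integer(removed),
                retained_count = as.integer(inputs - removed))
  .assert(all(out$retained_count >= 0), "cascade removes more than available")
  validate_ledger(filter_ledger(stages = out))
  out
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("lincRNA discovery filter ledger\n")
  print(x$stages, n = Inf)
  invisible(x)
}

#' @export
tidy.filter_ledger <- function(x, ...) x$stages

#' @export
glance.filter_ledger <- function(x, ...) {
  tibble(
    n_stages = nrow(x$stages),
    input_count = if (nrow(x$stages)) x$stages$input_count[1] else 0L,
    retained_count = if (nrow(x$stages)) tail(x$stages$retained_count, 1) else 0L,
    removed_total = sum(x$stages$removed_count)
  )
}
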