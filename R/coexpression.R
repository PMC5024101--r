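#' Spearman co-expression between lincRNAs and mRNAs
#'
#' Computes the Spearman rank correlation (average ranks, with tie correction,
#' as implemented by [stats::cor()]) between every lincRNA row and every mRNA
#' row over the shared tissue panel. Rows with zero variance have no defined
#' rank correlation; their pairs are reported with `rho = 0` and
#' `flagged = TRUE` rather than silently dropped.
#'
#' @param linc_expr,mrna_expr FPKM tibbles ([read_fpkm()] layout) with
#'   identical tissue columns (at least 3 tissues).
#' @return Object of class `coexpression`: list with `pairs` (tibble:
#'   `linc_id`, `mrna_id`, `rho`, `flagged`) and `tissues`.
#' @export
spearman_coexpression <- function(linc_expr, mrna_expr) {
  lt <- setdiff(names(linc_expr), "transcript_id")
  mt <- setdiff(names(mrna_expr), "transcript_id")
  if (!identical(lt, mt)) {
    stop("tissue columns differ between the two expression matrices",
         call. = FALSE)
  }
  .assert(length(lt) >= 3, "need at least 3 tissues for rank correlation")
  A <- fpkm_matrix(linc_expr)
  B <- fpkm_matrix(mrna_expr)
  flat_a <- apply(A, 1, function(x) stats::sd(x) == 0)
  flat_b <- apply(B, 1, function(x) stats::sd(x) == 0)
  suppressWarnings(
    rho <- stats::cor(t(A), t(B), method = "spearman")
  )
  pairs <- as_tibble(as.data.frame.table(rho, responseName = "rho",
                                         stringsAsFactors = FALSE)) %>%
    rename(linc_id = "Var1", mrna_id = "Var2") %>%
    mutate(flagged = flat_a[.data$linc_id] | flat_b[.data$mrna_id],
           rho = ifelse(is.na(.data$rho), 0, .data$rho))
  structure(list(pairs = pairs, tissues = lt), class = "coexpression")
}

#' @export
print.coexpression <- function(x, ...) {
  cat(sprintf("co-expression: %d pairs over %d tissues (%d flagged)\n",
              nrow(x$pairs), length(x$tissues), sum(x$pairs$flagged)))
  invisible(x)
}

#' @describeIn spearman_coexpression `tidy()` returns the long pair table.
#' @param x A `coexpression` object.
#' @param ... Unused.
#' @export
tidy.coexpression <- function(x, ...) x$pairs

#' Top co-expressed mRNAs of a lincRNA
#'
#' Extracts the `k` mRNAs with the highest Spearman correlation to the given
#' lincRNA; exact ties are ordered lexicographically by mRNA id. Fewer than
#' `k` are returned when fewer mRNAs exist.
#'
#' @param coexpr A [spearman_coexpression()] result.
#' @param linc_id LincRNA identifier present in the result.
#' @param k Number of mRNAs to return.
#' @return Tibble: `rank`, `mrna_id`, `rho`.
#' @export
top_coexpressed <- function(coexpr, linc_id, k = 10L) {
  sub <- coexpr$pairs %>% filter(.data$linc_id == !!linc_id)
  if (!nrow(sub)) stop("unknown lincRNA id: ", linc_id, call. = FALSE)
  sub %>%
    arrange(dplyr::desc(.data$rho), .data$mrna_id) %>%
    head(k) %>%
    mutate(rank = row_number()) %>%
    select("rank", "mrna_id", "rho")
}
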