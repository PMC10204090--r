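#' Decide whether a member assignment forms a plausible operon
#'
#' A candidate operon is a set of genes, one per chain step, that share a
#' replicon and a strand and sit close together: consecutive members (in
#' genomic order) may be separated by at most `gap_tolerance` non-member
#' genes. The result is invariant to the input order of the assignment's
#' genes, and the members' genomic order need not equal the chain's step
#' order unless `require_collinear` is set.
#'
#' @param members feature tibble for one assignment (one row per chain step,
#'   with a `step` column and gene `index` values from the feature table).
#' @param gap_tolerance maximum number of intervening non-member genes
#'   between consecutive members (default 2).
#' @param require_collinear require genomic order of members to match chain
#'   step order, read 5' to 3' on the operon strand (default `FALSE`).
#' @return a one-row tibble describing the operon (`replicon`, `strand`,
#'   `members` list-column in genomic order, `member_tags`, `upstream_index`,
#'   `upstream_tag`, `span`), or `NULL` when the assignment does not qualify.
#' @export
detect_operon <- function(members, gap_tolerance = 2, require_collinear = FALSE) {
  stopifnot(is_tibble(members), nrow(members) >= 1)
  if (length(unique(members$genomic_accession)) > 1) return(NULL)
  if (length(unique(members$strand)) > 1) return(NULL)
  if (anyDuplicated(members$index) > 0) return(NULL)
  ord <- arrange(members, index)
  gaps <- diff(ord$index) - 1L
  if (any(gaps > gap_tolerance)) return(NULL)
  strand <- ord$strand[1]
  if (require_collinear) {
    step_in_genomic_order <- if (strand == "+") ord$step else rev(ord$step)
    if (!identical(step_in_genomic_order, sort(ord$step))) return(NULL)
  }
  upstream <- if (strand == "+") ord[1, ] else ord[nrow(ord), ]
  tibble(
    replicon = ord$genomic_accession[1],
    strand = strand,
    members = list(ord),
    member_tags = paste(ord$locus_tag, collapse = ";"),
    upstream_index = upstream$index,
    upstream_tag = upstream$locus_tag,
    span = max(ord$end) - min(ord$start)
  )
}
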