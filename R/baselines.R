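# SNP-based baseline scorers: GWAS p-value aggregation (SNP-PV) and
# summed signed eQTL effects (SNP-eQTL).

#' Validate a gene-disease association table
#'
#' @param records Data frame with columns `gene_id`, `disease_id`,
#'   `value`.
#' @param kind `"pvalue"` (GWAS p-values, must lie in (0, 1]) or `"eqtl"`
#'   (signed effects, any finite real).
#' @return The records as a tibble with a `kind` attribute.
#' @export
gene_association_table <- function(records, kind = c("pvalue", "eqtl")) {
  kind <- match.arg(kind)
  records <- tibble::as_tibble(records)
  stopifnot(all(c("gene_id", "disease_id", "value") %in% names(records)))
  if (kind == "pvalue" &&
      any(records$value <= 0 | records$value > 1)) {
    vq_abort("p-values must lie in (0, 1]", "vqtarget_label_error")
  }
  if (any(!is.finite(records$value))) {
    vq_abort("association values must be finite",
             "vqtarget_nonfinite_error")
  }
  attr(records, "kind") <- kind
  records
}

#' GWAS p-value baseline score
#'
#' Genes reported with several SNPs or by several studies have their
#' p-values averaged; the predictive score is `-log(mean p)` (base 10 by
#' default), higher meaning a stronger candidate.
#'
#' @param table A gene-disease p-value table (see
#'   [gene_association_table()]); may span several diseases.
#' @param log_base Base of the logarithm (GWAS convention: 10).
#' @return A tibble with `disease_id`, `gene_id`, `score`.
#' @export
snp_pv_score <- function(table, log_base = 10) {
  table <- gene_association_table(table, kind = "pvalue")
  table |>
    dplyr::group_by(.data$disease_id, .data$gene_id) |>
    dplyr::summarise(score = -log(mean(.data$value), base = log_base),
                     .groups = "drop")
}

#' Summed eQTL baseline score with direction call
#'
#' Each gene's signed eQTL effects are summed per disease. Strongly
#' positive sums nominate inhibitory targets, strongly negative sums
#' activatory targets; for ranking, the inhibitory list uses `+score` and
#' the activatory list `-score`.
#'
#' @param table A gene-disease eQTL effect table.
#' @return A tibble with `disease_id`, `gene_id`, `score`, `direction`
#'   (`"inhibitory"`, `"activatory"` or `"none"`), and the two ranking
#'   scores `inhibitory_score`, `activatory_score`.
#' @export
snp_eqtl_score <- function(table) {
  table <- gene_association_table(table, kind = "eqtl")
  table |>
    dplyr::group_by(.data$disease_id, .data$gene_id) |>
    dplyr::summarise(score = sum(.data$value), .groups = "drop") |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$score > 0 ~ "inhibitory",
        .data$score < 0 ~ "activatory",
        TRUE ~ "none"
      ),
      inhibitory_score = .data$score,
      activatory_score = -.data$score
    )
}
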