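# Data model and I/O for expression inputs: perturbation tensors,
# disease/patient cohorts, and protein-disease label tables.

# ---- perturbation tensor -----------------------------------------------

#' Construct a protein perturbation tensor
#'
#' A perturbation tensor holds differential-expression profiles indexed by
#' protein, cell type and gene, as produced by knockdown (inhibitory
#' direction) or overexpression (activatory direction) experiments. A
#' logical protein-by-cell mask records which slices were never measured.
#'
#' @param values Numeric array of dimension `n_proteins x n_cells x n_genes`.
#' @param protein_ids,cell_ids,gene_ids Unique identifier vectors matching
#'   the array dimensions.
#' @param missing Logical protein-by-cell matrix marking unmeasured slices.
#'   Defaults to all observed.
#' @param direction `"inhibitory"` (knockdown) or `"activatory"`
#'   (overexpression).
#' @return An object of class `perturbation_tensor`.
#' @export
perturbation_tensor <- function(values, protein_ids, cell_ids, gene_ids,
                                missing = NULL,
                                direction = c("inhibitory", "activatory")) {
  direction <- match.arg(direction)
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    vq_abort("`values` must be a 3-d array (protein x cell x gene)",
             "vqtarget_shape_error")
  }
  dims <- dim(values)
  if (dims[1] != length(protein_ids) || dims[2] != length(cell_ids) ||
      dims[3] != length(gene_ids)) {
    vq_abort("tensor dimensions do not match id vectors",
             "vqtarget_shape_error")
  }
  assert_unique_ids(protein_ids, "protein", "vqtarget_duplicate_id")
  assert_unique_ids(cell_ids, "cell", "vqtarget_duplicate_id")
  assert_unique_ids(gene_ids, "gene", "vqtarget_duplicate_id")
  if (is.null(missing)) {
    missing <- matrix(FALSE, dims[1], dims[2])
  }
  missing <- matrix(as.logical(missing), dims[1], dims[2])
  dimnames(values) <- list(protein_ids, cell_ids, gene_ids)
  dimnames(missing) <- list(protein_ids, cell_ids)
  observed <- values[!array(missing, dim = dims)]
  if (any(!is.finite(observed))) {
    vq_abort("observed tensor entries must all be finite",
             "vqtarget_nonfinite_error")
  }
  structure(
    list(values = values, protein_ids = as.character(protein_ids),
         cell_ids = as.character(cell_ids), gene_ids = as.character(gene_ids),
         missing = missing, direction = direction),
    class = "perturbation_tensor"
  )
}

#' @export
print.perturbation_tensor <- function(x, ...) {
  cat(sprintf(
    "<perturbation_tensor> %d proteins x %d cells x %d genes (%s), %d missing slice(s)\n",
    length(x$protein_ids), length(x$cell_ids), length(x$gene_ids),
    x$direction, sum(x$missing)
  ))
  invisible(x)
}

#' Tidy a perturbation tensor into long format
#'
#' @param x A `perturbation_tensor`.
#' @param ... Unused.
#' @return A tibble with columns `protein_id`, `cell_id`, `gene_id`, `value`.
#' @method tidy perturbation_tensor
#' @export
tidy.perturbation_tensor <- function(x, ...) {
  grid <- tidyr::expand_grid(
    gene_id = x$gene_ids, cell_id = x$cell_ids, protein_id = x$protein_ids
  )
  out <- tibble::tibble(
    protein_id = grid$protein_id,
    cell_id = grid$cell_id,
    gene_id = grid$gene_id,
    value = as.vector(x$values)
  )
  dplyr::arrange(out, .data$protein_id, .data$cell_id, .data$gene_id)
}

# ---- matrix readers/writers --------------------------------------------

#' Read a tab-delimited expression matrix
#'
#' Expects one header row of sample (column) ids and a first column of row
#' ids, the layout used for gene-by-sample expression tables.
#'
#' @param path Path to a tab-delimited file.
#' @param genes_in_rows Logical; if `TRUE` (default) rows are genes and the
#'   matrix is returned as read, otherwise it is transposed so that rows are
#'   samples.
#' @return A numeric matrix with row and column names in file order.
#' @export
read_expression_matrix <- function(path, genes_in_rows = TRUE) {
  if (!file.exists(path)) {
    vq_abort(sprintf("file not found: %s", path), "vqtarget_io_error")
  }
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1])[1]
    vq_abort(
      sprintf("ragged row in %s: line %d has %d fields, expected %d",
              path, bad, fields[bad], fields[1]),
      "vqtarget_parse_error"
    )
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) {
    vq_abort("expected an id column plus at least one data column",
             "vqtarget_parse_error")
  }
  ids <- raw[[1]]
  assert_unique_ids(ids, "row", "vqtarget_duplicate_id")
  assert_unique_ids(colnames(raw)[-1], "column", "vqtarget_duplicate_id")
  body <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (any(is.na(num) & !is.na(body) & body != "NA")) {
    bad <- which(is.na(num) & body != "NA", arr.ind = TRUE)[1, ]
    vq_abort(
      sprintf("non-numeric value %s at row '%s', column '%s'",
              dQuote(body[bad[1], bad[2]]), ids[bad[1]],
              colnames(raw)[-1][bad[2]]),
      "vqtarget_parse_error"
    )
  }
  dimnames(num) <- list(ids, colnames(raw)[-1])
  if (genes_in_rows) num else t(num)
}

#' Write a tab-delimited expression matrix
#'
#' Inverse of [read_expression_matrix()]: first column holds row ids under
#' the header `id`, remaining columns are the matrix columns.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- replicate averaging ------------------------------------------------

#' Average biological replicates into a perturbation tensor
#'
#' Replicate profiles for the same protein and cell type are averaged
#' element-wise; protein-by-cell combinations with no replicate are marked
#' missing in the returned tensor.
#'
#' @param replicates A data frame with columns `protein_id`, `cell_id` and a
#'   list-column `profile` of equal-length numeric gene vectors.
#' @param gene_ids Gene identifiers for the profile entries; defaults to the
#'   names of the first profile or `g1..ga`.
#' @param direction Perturbation direction, see [perturbation_tensor()].
#' @param cell_ids,protein_ids Optional full id universes (defaults: ids
#'   present in `replicates`, in order of first appearance).
#' @return A [perturbation_tensor()].
#' @export
average_replicates <- function(replicates, gene_ids = NULL,
                               direction = c("inhibitory", "activatory"),
                               protein_ids = NULL, cell_ids = NULL) {
  direction <- match.arg(direction)
  stopifnot(all(c("protein_id", "cell_id", "profile") %in% names(replicates)))
  lens <- lengths(replicates$profile)
  if (length(unique(lens)) > 1L) {
    vq_abort("replicate profiles have inconsistent lengths",
             "vqtarget_shape_error")
  }
  a <- lens[1]
  if (is.null(gene_ids)) {
    gene_ids <- names(replicates$profile[[1]]) %||% paste0("g", seq_len(a))
  }
  protein_ids <- protein_ids %||% unique(replicates$protein_id)
  cell_ids <- cell_ids %||% unique(replicates$cell_id)

  values <- array(NA_real_,
                  dim = c(length(protein_ids), length(cell_ids), a))
  missing <- matrix(TRUE, length(protein_ids), length(cell_ids))
  grouped <- dplyr::group_by(tibble::as_tibble(replicates),
                             .data$protein_id, .data$cell_id)
  means <- dplyr::summarise(
    grouped,
    profile = list(Reduce(`+`, .data$profile) / length(.data$profile)),
    .groups = "drop"
  )
  for (i in seq_len(nrow(means))) {
    s <- match(means$protein_id[i], protein_ids)
    c_ <- match(means$cell_id[i], cell_ids)
    values[s, c_, ] <- means$profile[[i]]
    missing[s, c_] <- FALSE
  }
  values[is.na(values)] <- 0
  perturbation_tensor(values, protein_ids, cell_ids, gene_ids,
                      missing = missing, direction = direction)
}

# ---- missing-slice imputation ------------------------------------------

#' Impute missing protein-by-cell slices
#'
#' Each missing entry (protein s, cell c, gene g) is filled with the mean of
#' two quantities: the protein's mean over its observed cells at gene g, and
#' the cell's mean over its observed proteins at gene g. The tensor's missing
#' mask is cleared. The rule is deliberately simple and idempotent; a richer
#' tensor-completion method can be substituted upstream of the pipeline.
#'
#' @param tensor A [perturbation_tensor()].
#' @return The tensor with all slices observed.
#' @export
impute_missing <- function(tensor) {
  stopifnot(inherits(tensor, "perturbation_tensor"))
  if (!any(tensor$missing)) {
    return(tensor)
  }
  obs <- !tensor$missing
  if (any(rowSums(obs) == 0)) {
    bad <- tensor$protein_ids[rowSums(obs) == 0][1]
    vq_abort(sprintf("protein '%s' has no observed slice", bad),
             "vqtarget_impute_error")
  }
  if (any(colSums(obs) == 0)) {
    bad <- tensor$cell_ids[colSums(obs) == 0][1]
    vq_abort(sprintf("cell '%s' has no observed slice", bad),
             "vqtarget_impute_error")
  }
  values <- tensor$values
  n_gene <- length(tensor$gene_ids)
  for (s in seq_along(tensor$protein_ids)) {
    for (c_ in seq_along(tensor$cell_ids)) {
      if (!tensor$missing[s, c_]) next
      cells_obs <- which(obs[s, ])
      prots_obs <- which(obs[, c_])
      # single-index slices drop to vectors; rebuild the replicate x gene shape
      protein_mean <- colMeans(
        array(values[s, cells_obs, ], dim = c(length(cells_obs), n_gene))
      )
      cell_mean <- colMeans(
        array(values[prots_obs, c_, ], dim = c(length(prots_obs), n_gene))
      )
      values[s, c_, ] <- (protein_mean + cell_mean) / 2
    }
  }
  perturbation_tensor(values, tensor$protein_ids, tensor$cell_ids,
                      tensor$gene_ids, missing = NULL,
                      direction = tensor$direction)
}

# ---- cohort profiles ----------------------------------------------------

#' Construct disease/patient cohort profiles
#'
#' Holds patient-level expression vectors, the patient-to-disease map, and
#' (optionally) disease-level profiles obtained by averaging each disease's
#' patients.
#'
#' @param patient_matrix Numeric patient-by-gene matrix with row names.
#' @param patient_to_disease A data frame with columns `patient_id`,
#'   `disease_id` (or a named character vector patient -> disease).
#' @param gene_ids Optional gene ids (default: column names).
#' @param disease_matrix Optional disease-by-gene matrix; usually built with
#'   [build_disease_profiles()].
#' @return An object of class `cohort_profiles`.
#' @export
cohort_profiles <- function(patient_matrix, patient_to_disease,
                            gene_ids = NULL, disease_matrix = NULL) {
  if (is.character(patient_to_disease) && !is.null(names(patient_to_disease))) {
    patient_to_disease <- tibble::tibble(
      patient_id = names(patient_to_disease),
      disease_id = unname(patient_to_disease)
    )
  }
  patient_to_disease <- tibble::as_tibble(patient_to_disease)
  stopifnot(all(c("patient_id", "disease_id") %in% names(patient_to_disease)))
  patient_matrix <- as.matrix(patient_matrix)
  gene_ids <- gene_ids %||% colnames(patient_matrix) %||%
    paste0("g", seq_len(ncol(patient_matrix)))
  colnames(patient_matrix) <- gene_ids
  patient_ids <- rownames(patient_matrix) %||%
    paste0("p", seq_len(nrow(patient_matrix)))
  rownames(patient_matrix) <- patient_ids
  assert_unique_ids(patient_ids, "patient", "vqtarget_duplicate_id")
  assert_unique_ids(patient_to_disease$patient_id, "patient",
                    "vqtarget_duplicate_id")
  if (!setequal(patient_to_disease$patient_id, patient_ids)) {
    vq_abort("every patient row must map to exactly one disease",
             "vqtarget_cohort_error")
  }
  if (any(!is.finite(patient_matrix))) {
    vq_abort("patient matrix must be finite", "vqtarget_nonfinite_error")
  }
  structure(
    list(patient_matrix = patient_matrix,
         disease_matrix = disease_matrix,
         patient_to_disease = patient_to_disease,
         patient_ids = patient_ids,
         disease_ids = if (!is.null(disease_matrix)) rownames(disease_matrix)
                       else unique(patient_to_disease$disease_id),
         gene_ids = gene_ids),
    class = "cohort_profiles"
  )
}

#' @export
print.cohort_profiles <- function(x, ...) {
  cat(sprintf(
    "<cohort_profiles> %d patients, %d diseases, %d genes (%s disease matrix)\n",
    length(x$patient_ids), length(x$disease_ids), length(x$gene_ids),
    if (is.null(x$disease_matrix)) "no" else "with"
  ))
  invisible(x)
}

#' Average patient profiles into disease profiles
#'
#' Produces one disease-level row per distinct disease, equal to the
#' arithmetic mean of that disease's patient rows.
#'
#' @param cohort A [cohort_profiles()] object (disease matrix ignored if
#'   already present).
#' @return The cohort with `disease_matrix` filled in.
#' @export
build_disease_profiles <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_profiles"))
  map <- cohort$patient_to_disease
  disease_ids <- unique(map$disease_id)
  counts <- table(map$disease_id)
  if (any(!(disease_ids %in% names(counts)))) {
    vq_abort("disease with zero patients in the id list",
             "vqtarget_cohort_error")
  }
  dm <- t(vapply(disease_ids, function(d) {
    pats <- map$patient_id[map$disease_id == d]
    colMeans(cohort$patient_matrix[pats, , drop = FALSE])
  }, numeric(length(cohort$gene_ids))))
  rownames(dm) <- disease_ids
  colnames(dm) <- cohort$gene_ids
  cohort$disease_matrix <- dm
  cohort$disease_ids <- disease_ids
  cohort
}

# ---- pair labels --------------------------------------------------------

#' Construct a protein-disease label table
#'
#' @param records A data frame with columns `protein_id`, `disease_id`,
#'   `label` (0/1).
#' @param unlabeled_diseases Character vector of profiled diseases with no
#'   labels (the uncharacterized set N).
#' @param direction Perturbation direction the labels refer to.
#' @return An object of class `labeled_pairs` with fields `records`
#'   (tibble), `known_diseases` (M), `unlabeled_diseases` (N),
#'   `known_proteins` (R) and `direction`.
#' @export
labeled_pairs <- function(records, unlabeled_diseases = character(),
                          direction = c("inhibitory", "activatory")) {
  direction <- match.arg(direction)
  records <- tibble::as_tibble(records)
  stopifnot(all(c("protein_id", "disease_id", "label") %in% names(records)))
  if (nrow(records) > 0 && !all(records$label %in% c(0, 1))) {
    bad <- records$label[!records$label %in% c(0, 1)][1]
    vq_abort(sprintf("labels must be 0 or 1, found %s", bad),
             "vqtarget_label_error")
  }
  known_diseases <- unique(records$disease_id)
  unlabeled_diseases <- setdiff(unique(unlabeled_diseases), known_diseases)
  structure(
    list(records = records,
         known_diseases = known_diseases,
         unlabeled_diseases = unlabeled_diseases,
         known_proteins = unique(records$protein_id),
         direction = direction),
    class = "labeled_pairs"
  )
}

#' @export
print.labeled_pairs <- function(x, ...) {
  cat(sprintf(
    "<labeled_pairs> %d records (%d positive), |M|=%d known diseases, |N|=%d uncharacterized, |R|=%d proteins (%s)\n",
    nrow(x$records), sum(x$records$label == 1),
    length(x$known_diseases), length(x$unlabeled_diseases),
    length(x$known_proteins), x$direction
  ))
  invisible(x)
}

#' Read a protein-disease label file
#'
#' @param path Tab-delimited file with columns `protein_id`, `disease_id`,
#'   `label`.
#' @param profiled_diseases Optional character vector of all diseases with
#'   profiles; those absent from the label file become the uncharacterized
#'   set N.
#' @param direction Perturbation direction tag.
#' @return A [labeled_pairs()] object.
#' @export
read_pair_labels <- function(path, profiled_diseases = NULL,
                             direction = c("inhibitory", "activatory")) {
  direction <- match.arg(direction)
  if (!file.exists(path)) {
    vq_abort(sprintf("file not found: %s", path), "vqtarget_io_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("protein_id", "disease_id", "label")
  n_set <- setdiff(profiled_diseases %||% character(), df$disease_id)
  labeled_pairs(df, unlabeled_diseases = n_set, direction = direction)
}
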