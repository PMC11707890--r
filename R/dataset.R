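#' Construct a perturbation dataset
#'
#' Pairs an n x q drug-concentration matrix `D` (one row per experimental
#' condition) with the n x p matrix `X` of measured responses in the same
#' conditions. Responses are changes relative to the unperturbed state, so
#' no intercept column is carried. Missing values are rejected: downstream
#' least-squares fits assume complete matrices.
#'
#' @param D n x q numeric matrix of drug concentrations.
#' @param X n x p numeric matrix of measured responses.
#' @param drug_names,response_names optional names (length q, p).
#' @param condition_ids optional condition identifiers (length n).
#' @return An object of class `perturbation_dataset`.
#' @export
perturbation_dataset <- function(D, X, drug_names = NULL,
                                 response_names = NULL,
                                 condition_ids = NULL) {
  D <- as_numeric_matrix(D, "D")
  X <- as_numeric_matrix(X, "X")
  if (nrow(D) != nrow(X)) {
    stop(sprintf("D has %d rows but X has %d; one row per condition required",
                 nrow(D), nrow(X)), call. = FALSE)
  }
  if (anyNA(D) || anyNA(X)) stop("missing values are not allowed", call. = FALSE)
  n <- nrow(D)
  drug_names <- drug_names %||% colnames(D) %||% paste0("D", seq_len(ncol(D)))
  response_names <- response_names %||% colnames(X) %||%
    paste0("X", seq_len(ncol(X)))
  condition_ids <- condition_ids %||% rownames(D) %||% paste0("cond", seq_len(n))
  check_length(drug_names, ncol(D), "drug_names")
  check_length(response_names, ncol(X), "response_names")
  check_length(condition_ids, n, "condition_ids")
  if (anyDuplicated(condition_ids)) {
    stop("condition_ids must be unique", call. = FALSE)
  }
  dimnames(D) <- list(condition_ids, drug_names)
  dimnames(X) <- list(condition_ids, response_names)
  structure(
    list(D = D, X = X, drug_names = as.character(drug_names),
         response_names = as.character(response_names),
         condition_ids = as.character(condition_ids)),
    class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  cat(sprintf("Perturbation dataset: %d conditions, %d drugs, %d responses\n",
              length(x$condition_ids), length(x$drug_names),
              length(x$response_names)))
  invisible(x)
}

#' Subset a perturbation dataset by condition
#'
#' @param data a [perturbation_dataset()].
#' @param ids condition identifiers to keep, in the order given.
#' @return A `perturbation_dataset` restricted to those conditions.
#' @export
subset_conditions <- function(data, ids) {
  stopifnot(inherits(data, "perturbation_dataset"))
  missing_ids <- setdiff(ids, data$condition_ids)
  if (length(missing_ids) > 0L) {
    stop("unknown condition ids: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  perturbation_dataset(data$D[ids, , drop = FALSE],
                       data$X[ids, , drop = FALSE],
                       drug_names = data$drug_names,
                       response_names = data$response_names,
                       condition_ids = ids)
}

#' Write a perturbation dataset as a pair of CSV files
#'
#' `drugs.csv` holds `condition_id` plus one column per drug; `responses.csv`
#' holds `condition_id` plus one column per response. Row order is preserved.
#'
#' @param data a [perturbation_dataset()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_perturbation_dataset <- function(data, dir) {
  stopifnot(inherits(data, "perturbation_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(drugs = file.path(dir, "drugs.csv"),
             responses = file.path(dir, "responses.csv"))
  write_matrix_csv(data$D, paths["drugs"])
  write_matrix_csv(data$X, paths["responses"])
  invisible(paths)
}

#' Read a perturbation dataset from drugs.csv / responses.csv
#'
#' Validates that the two files list the same condition identifiers in the
#' same order and contain no missing values.
#'
#' @param dir directory containing `drugs.csv` and `responses.csv`, or
#'   explicit paths via `drugs_path` / `responses_path`.
#' @param drugs_path,responses_path explicit file paths (override `dir`).
#' @return A [perturbation_dataset()].
#' @export
read_perturbation_dataset <- function(dir = NULL, drugs_path = NULL,
                                      responses_path = NULL) {
  drugs_path <- drugs_path %||% file.path(dir, "drugs.csv")
  responses_path <- responses_path %||% file.path(dir, "responses.csv")
  D <- read_matrix_csv(drugs_path)
  X <- read_matrix_csv(responses_path)
  if (!identical(rownames(D), rownames(X))) {
    stop("condition ids differ between drug and response files", call. = FALSE)
  }
  perturbation_dataset(D, X)
}
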