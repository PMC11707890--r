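#' Read a named numeric matrix from CSV
#'
#' Expects a header row and a first column of row identifiers (condition or
#' response ids); the body must be rectangular and fully numeric. Row order
#' is preserved. Ragged rows, non-numeric cells, missing cells and
#' duplicated names are rejected with the offending line or cell named.
#'
#' @param path path to a CSV file.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file has no data rows: ", path, call. = FALSE)
  # sentinel keeps trailing empty cells, which strsplit would otherwise drop
  fields <- lapply(strsplit(paste0(lines, "\r"), ",", fixed = TRUE),
                   function(f) {
                     f[length(f)] <- sub("\r$", "", f[length(f)])
                     f
                   })
  header <- fields[[1L]]
  ncol_expect <- length(header)
  col_names <- header[-1L]
  if (anyDuplicated(col_names)) {
    stop("duplicate column names in ", path, call. = FALSE)
  }
  body <- fields[-1L]
  n <- length(body)
  row_names <- character(n)
  M <- matrix(NA_real_, n, ncol_expect - 1L)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != ncol_expect) {
      stop(sprintf("line %d of %s has %d fields, expected %d",
                   i + 1L, path, length(row), ncol_expect), call. = FALSE)
    }
    row_names[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(is.na(vals) | row[-1L] == "")
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric or missing cell at line %d, column '%s' of %s",
        i + 1L, col_names[bad[1L]], path), call. = FALSE)
    }
    M[i, ] <- vals
  }
  if (anyDuplicated(row_names)) {
    stop("duplicate row names in ", path, call. = FALSE)
  }
  dimnames(M) <- list(row_names, col_names)
  M
}

#' Write a named numeric matrix as CSV
#'
#' Inverse of [read_matrix_csv()]: header row with an `id` corner cell,
#' one identifier column, full decimal precision, "." decimal separator.
#'
#' @param M numeric matrix with dimnames.
#' @param path output path.
#' @param id_label label for the identifier column (default "id").
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(M, path, id_label = "id") {
  M <- as_numeric_matrix(M, "M")
  rn <- rownames(M) %||% paste0("row", seq_len(nrow(M)))
  cn <- colnames(M) %||% paste0("col", seq_len(ncol(M)))
  lines <- c(paste(c(id_label, cn), collapse = ","),
             vapply(seq_len(nrow(M)), function(i) {
               paste(c(rn[i], format(M[i, ], digits = 17, trim = TRUE,
                                     scientific = FALSE)),
                     collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# ---- model / SEM serialization -----------------------------------------

serialize_payload <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 17)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  }
  invisible(path)
}

deserialize_payload <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  }
}

rows_to_matrix <- function(rows, rownames = NULL, colnames = NULL) {
  M <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(M) <- list(rownames, colnames)
  M
}

matrix_to_rows <- function(M) lapply(seq_len(nrow(M)), function(i) unname(M[i, ]))

#' Serialize a causal SEM to YAML or JSON
#'
#' A single document holding A and B as row-major nested lists, the noise
#' scale, optional noise covariance, and the name lists. The format is
#' chosen from the file extension (`.yaml`/`.yml` or anything else = JSON).
#' Values representable in decimal round-trip exactly.
#'
#' @param sem a [causal_sem()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sem <- function(sem, path) {
  stopifnot(inherits(sem, "causal_sem"))
  payload <- list(type = "causal_sem",
                  response_names = sem$response_names,
                  drug_names = sem$drug_names,
                  A = matrix_to_rows(sem$A),
                  B = matrix_to_rows(sem$B),
                  noise_sd = sem$noise_sd)
  if (!is.null(sem$noise_cov)) payload$noise_cov <- matrix_to_rows(sem$noise_cov)
  serialize_payload(payload, path)
}

#' @rdname write_sem
#' @export
read_sem <- function(path) {
  x <- deserialize_payload(path)
  if (!identical(x$type, "causal_sem")) {
    stop("not a serialized causal SEM: ", path, call. = FALSE)
  }
  causal_sem(A = rows_to_matrix(x$A), B = rows_to_matrix(x$B),
             noise_sd = x$noise_sd,
             response_names = unlist(x$response_names),
             drug_names = unlist(x$drug_names),
             noise_cov = if (is.null(x$noise_cov)) NULL else
               rows_to_matrix(x$noise_cov))
}

#' Serialize a fitted model to YAML or JSON
#'
#' Supports `lr_model`, `csr_model` and `cellbox_model` objects. Matrices
#' are stored as row-major nested lists together with the fitting metadata
#' (lambda, zeroed drugs, positive-definiteness report, objective value).
#'
#' @param model a fitted model object.
#' @param path output path (`.yaml`/`.yml` for YAML, otherwise JSON).
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  payload <- if (inherits(model, "lr_model")) {
    list(type = "lr_model", R = matrix_to_rows(model$R),
         lambda = model$lambda, zeroed_drugs = as.list(model$zeroed_drugs),
         drug_names = model$drug_names, response_names = model$response_names)
  } else if (inherits(model, "csr_model")) {
    list(type = "csr_model", T = matrix_to_rows(model$T),
         A_hat = if (is.null(model$A_hat)) NULL else matrix_to_rows(model$A_hat),
         pd_report = model$pd_report, lambda = model$lambda,
         objective = model$objective,
         B = if (is.null(model$B)) NULL else matrix_to_rows(model$B),
         drug_names = model$drug_names, response_names = model$response_names)
  } else if (inherits(model, "cellbox_model")) {
    list(type = "cellbox_model", W = matrix_to_rows(model$W),
         tau = model$tau, envelope = model$envelope, stable = model$stable,
         response_names = model$response_names)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  serialize_payload(payload, path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- deserialize_payload(path)
  rn <- unlist(x$response_names)
  switch(
    x$type %||% "unknown",
    lr_model = structure(
      list(R = rows_to_matrix(x$R, rn, unlist(x$drug_names)),
           lambda = x$lambda, zeroed_drugs = unlist(x$zeroed_drugs) %||% character(),
           drug_names = unlist(x$drug_names), response_names = rn),
      class = "lr_model"),
    csr_model = structure(
      list(T = rows_to_matrix(x$T, rn, rn),
           A_hat = if (is.null(x$A_hat)) NULL else rows_to_matrix(x$A_hat, rn, rn),
           pd_report = x$pd_report, lambda = x$lambda,
           objective = x$objective,
           B = if (is.null(x$B)) NULL else
             rows_to_matrix(x$B, rn, unlist(x$drug_names)),
           mask = NULL, seed = NULL,
           drug_names = unlist(x$drug_names), response_names = rn),
      class = "csr_model"),
    cellbox_model = cellbox_model(W = rows_to_matrix(x$W, rn, rn),
                                  response_names = rn),
    stop("not a serialized model: ", path, call. = FALSE))
}

#' Write a structure network as an edge-list CSV
#'
#' @param A structure matrix or `causal_sem`.
#' @param path output path.
#' @param threshold minimum absolute weight (default 0.2; see
#'   [network_edges()]).
#' @return Invisibly, `path`.
#' @export
write_network_csv <- function(A, path, threshold = 0.2) {
  utils::write.csv(network_edges(A, threshold), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
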