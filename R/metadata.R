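#' Default host/biogeography feature columns
#'
#' The ten categorical attributes used for clade prediction: host class
#' (CatHC), order (CatHO), family (CatHF), genus (CatHG), species (CatHS);
#' habitat (CatE1), aquatic-ecosystem type (CatE2); zoogeographical region
#' (CatL1), continent (CatL2), country/river basin (CatL5).
#'
#' @export
cf_features <- function() {
  c("CatHC", "CatHO", "CatHF", "CatHG", "CatHS",
    "CatE1", "CatE2", "CatL1", "CatL2", "CatL5")
}

.normalize_missing <- function(df, features) {
  for (f in features) {
    v <- as.character(df[[f]])
    v[.is_missing_state(v)] <- NA_character_
    df[[f]] <- v
  }
  df
}

#' Curate a terminal-level metadata table
#'
#' Applies, in order: (1) drop rows whose host role is `intermediate` or
#' `paratenic`; (2) restrict columns to the requested features; (3) drop any
#' feature column whose missingness exceeds `col_missing_threshold`
#' (default 1, i.e. only fully-missing columns are dropped, so the feature
#' set is preserved whenever any data exist); (4) drop rows with any
#' remaining missing cell; (5) drop rows without a clade label. An optional
#' synonym map is applied to cell values before anything else.
#'
#' @param raw Data frame keyed by terminal (rownames, or a `terminal`
#'   column); cells are category strings, with `""`, `"?"`, `"NA"` or `NA`
#'   read as missing.
#' @param features Ordered character vector of feature columns
#'   (default [cf_features()]).
#' @param labels Named character vector terminal -> clade name
#'   (`"UNASSIGNED"` or `NA` = unlabelled), e.g. from [label_terminals()].
#' @param role_col Name of the host-role column, if present
#'   (values `definitive`, `intermediate`, `paratenic`).
#' @param col_missing_threshold Maximum tolerated per-column missingness
#'   fraction in (0, 1].
#' @param synonyms Optional named character vector `old -> new` applied to
#'   all feature cells before curation.
#' @return A list of class `cf_curated`: `table` (curated data frame with
#'   terminal rownames), `labels` (aligned clade names), and `report`
#'   (row/column counts dropped at each step).
#' @export
curate <- function(raw, features = cf_features(), labels,
                   role_col = "host_role", col_missing_threshold = 1,
                   synonyms = NULL) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  if ("terminal" %in% names(raw) && !identical(rownames(raw), raw$terminal)) {
    rownames(raw) <- raw$terminal
  }
  missing_feats <- setdiff(features, names(raw))
  if (length(missing_feats))
    stop("requested feature(s) absent from table: ",
         paste(missing_feats, collapse = ", "))
  if (col_missing_threshold <= 0 || col_missing_threshold > 1)
    stop("`col_missing_threshold` must be in (0, 1]")
  report <- list(rows_in = nrow(raw), features_in = length(features))

  if (!is.null(synonyms)) {
    for (f in features) {
      hit <- raw[[f]] %in% names(synonyms)
      raw[[f]][hit] <- unname(synonyms[raw[[f]][hit]])
    }
  }

  # (1) host-role filter
  n0 <- nrow(raw)
  if (role_col %in% names(raw)) {
    raw <- raw[!(raw[[role_col]] %in% c("intermediate", "paratenic")), ,
               drop = FALSE]
  }
  report$dropped_role <- n0 - nrow(raw)
  if (!nrow(raw)) stop("no rows left after host-role filtering (step 1)")

  # (2) feature restriction
  tab <- .normalize_missing(raw[, features, drop = FALSE], features)

  # (3) over-missing columns
  miss_frac <- vapply(tab, function(v) mean(is.na(v)), numeric(1))
  drop_cols <- names(miss_frac)[miss_frac == 1 |
                                  miss_frac > col_missing_threshold]
  report$dropped_columns <- drop_cols
  tab <- tab[, setdiff(names(tab), drop_cols), drop = FALSE]
  if (!ncol(tab)) stop("no feature columns left after missingness filter (step 3)")

  # (4) rows with missing cells
  n0 <- nrow(tab)
  keep <- !apply(tab, 1L, anyNA)
  tab <- tab[keep, , drop = FALSE]
  report$dropped_missing_rows <- n0 - nrow(tab)
  if (!nrow(tab)) stop("no rows left after missing-data removal (step 4)")

  # (5) rows without a clade label
  lab <- labels[rownames(tab)]
  lab[is.na(lab)] <- "UNASSIGNED"
  n0 <- nrow(tab)
  keep <- lab != "UNASSIGNED"
  tab <- tab[keep, , drop = FALSE]
  lab <- lab[keep]
  report$dropped_unlabelled <- n0 - nrow(tab)
  if (!nrow(tab)) stop("no rows left after clade-label filter (step 5)")

  report$rows_out <- nrow(tab)
  report$features_out <- ncol(tab)
  structure(list(table = tab, labels = setNames(as.character(lab),
                                                rownames(tab)),
                 report = report),
            class = "cf_curated")
}

#' @export
print.cf_curated <- function(x, ...) {
  r <- x$report
  cat("Curated metadata table: ", r$rows_out, " rows x ", r$features_out,
      " features (", r$rows_out * r$features_out, " data points)\n", sep = "")
  cat("  dropped: ", r$dropped_role, " intermediate/paratenic rows, ",
      r$dropped_missing_rows, " rows with missing data, ",
      r$dropped_unlabelled, " unlabelled rows",
      if (length(r$dropped_columns))
        paste0("; columns: ", paste(r$dropped_columns, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' One-hot encode a curated metadata table
#'
#' Expands each categorical feature into one binary indicator column per
#' observed value, named `feature=value`; columns are ordered by feature,
#' then by first observation within feature. The category-to-column mapping
#' (the encoder) is retained so new rows can be encoded identically.
#'
#' @param curated A `cf_curated` from [curate()], or a fully-curated data
#'   frame (no missing cells) with terminal rownames.
#' @param labels Aligned clade labels (taken from `curated` when it is a
#'   `cf_curated`).
#' @return A list of class `cf_encoded`: binary integer matrix `X`
#'   (terminals x columns), `labels`, and `encoder` (feature -> value levels).
#' @export
one_hot <- function(curated, labels = NULL) {
  if (inherits(curated, "cf_curated")) {
    if (is.null(labels)) labels <- curated$labels
    tab <- curated$table
  } else tab <- as.data.frame(curated, stringsAsFactors = FALSE)
  tab <- .normalize_missing(tab, names(tab))
  if (anyNA(tab))
    stop("missing cell encountered: table must be curated before encoding")
  encoder <- lapply(tab, function(v) unique(as.character(v)))
  X <- do.call(cbind, lapply(names(tab), function(f) {
    levs <- encoder[[f]]
    m <- matrix(0L, nrow(tab), length(levs),
                dimnames = list(rownames(tab), paste0(f, "=", levs)))
    m[cbind(seq_len(nrow(tab)), match(tab[[f]], levs))] <- 1L
    m
  }))
  if (!is.null(labels)) {
    if (is.null(names(labels))) {
      stopifnot(length(labels) == nrow(X))
      names(labels) <- rownames(X)
    }
    labels <- setNames(as.character(labels[rownames(X)]), rownames(X))
  }
  structure(list(X = X, labels = labels, encoder = encoder),
            class = "cf_encoded")
}

#' Encode new rows with an existing encoder
#'
#' @param encoder Encoder component of a `cf_encoded` (feature -> levels).
#' @param table Curated data frame with the encoder's features.
#' @return Binary integer matrix with exactly the encoder's columns; a value
#'   unseen at training time yields all-zero indicators for that feature.
#' @export
apply_encoder <- function(encoder, table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  absent <- setdiff(names(encoder), names(table))
  if (length(absent))
    stop("table lacks encoded feature(s): ", paste(absent, collapse = ", "))
  do.call(cbind, lapply(names(encoder), function(f) {
    levs <- encoder[[f]]
    m <- matrix(0L, nrow(table), length(levs),
                dimnames = list(rownames(table), paste0(f, "=", levs)))
    idx <- match(as.character(table[[f]]), levs)
    ok <- !is.na(idx)
    m[cbind(which(ok), idx[ok])] <- 1L
    m
  }))
}

#' Decode a one-hot matrix back to the categorical table
#'
#' Exact inverse of [one_hot()] for matrices produced by it.
#'
#' @param encoded A `cf_encoded` object.
#' @return Data frame of categorical features, terminal rownames preserved.
#' @export
decode_one_hot <- function(encoded) {
  stopifnot(inherits(encoded, "cf_encoded"))
  X <- encoded$X
  out <- lapply(names(encoded$encoder), function(f) {
    levs <- encoded$encoder[[f]]
    cols <- X[, paste0(f, "=", levs), drop = FALSE]
    if (any(rowSums(cols) != 1L))
      stop("matrix is not a valid one-hot encoding of feature ", f)
    levs[max.col(cols)]
  })
  names(out) <- names(encoded$encoder)
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  rownames(df) <- rownames(X)
  df
}

#' Summarize a curated metadata table
#'
#' @param table Curated data frame (or `cf_curated`).
#' @return List: `rows`, `features`, `data_points` (rows x features), and
#'   named `cardinality` (distinct values per feature).
#' @export
summarize_metadata <- function(table) {
  if (inherits(table, "cf_curated")) table <- table$table
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  card <- vapply(table, function(v) length(unique(v[!is.na(v)])),
                 integer(1))
  if (!ncol(table)) card <- setNames(integer(0), character(0))
  list(rows = nrow(table), features = ncol(table),
       data_points = nrow(table) * ncol(table), cardinality = card)
}

#' Metadata CSV input/output
#'
#' Tables are UTF-8 comma-separated files with a header row and a `terminal`
#' key column.
#'
#' @param file CSV path.
#' @return `read_metadata`: data frame with terminal rownames.
#' @export
read_metadata <- function(file) {
  if (!file.exists(file)) stop("metadata file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"terminal" %in% names(df))
    stop("metadata CSV needs a `terminal` column")
  if (anyDuplicated(df$terminal))
    stop("duplicate terminal identifiers in metadata CSV")
  rownames(df) <- df$terminal
  df[, setdiff(names(df), "terminal"), drop = FALSE]
}

#' @rdname read_metadata
#' @param table Data frame with terminal rownames.
#' @export
write_metadata <- function(table, file) {
  if (inherits(table, "cf_curated")) table <- table$table
  out <- cbind(terminal = rownames(table),
               as.data.frame(table, stringsAsFactors = FALSE))
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Persist / restore a one-hot encoder as JSON
#'
#' @param encoder Encoder (feature -> value levels) from [one_hot()].
#' @param file JSON path.
#' @export
write_encoder <- function(encoder, file) {
  jsonlite::write_json(encoder, file, auto_unbox = FALSE)
  invisible(file)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(file) {
  lapply(jsonlite::read_json(file, simplifyVector = TRUE), as.character)
}
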