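#' Default column schema of a community table
#'
#' The survey layout this package targets records, for every subplot and
#' year, the adult counts of each annual plant species together with 13 soil
#' variables measured once per subplot and the annual precipitation shared by
#' all subplots of a year. Species are labelled by four-letter codes.
#'
#' @return a list with elements `id` (identifier columns), `abiotic`
#'   (13 soil variables plus `precipitation`) and `species` (23 codes).
#' @export
default_schema <- function() {
  list(
    id = c("plot", "subplot", "year", "x", "y"),
    abiotic = c("pH", "salinity", "carbonates", "organic_matter", "cn_ratio",
                "Cl", "C", "N", "P", "Ca", "Mg", "K", "Na", "precipitation"),
    species = c("ANAR", "BEMA", "CETE", "CHFU", "CHMI", "COSQ", "FRPU",
                "HOMA", "LEMA", "LYTR", "MEEL", "MEPO", "MESU", "PAIN",
                "PLCO", "POMA", "POMO", "PUPA", "SASO", "SCLA", "SOAS",
                "SPRU", "SUSP")
  )
}

#' Construct a community table
#'
#' A community table is a tidy wide data frame with one row per
#' (plot, subplot, year) community, carrying subplot coordinates, abiotic
#' measurements and the integer abundance of every species. The species and
#' abiotic column sets are stored as attributes and preserved by the
#' package's own operations.
#'
#' @param df a data frame containing the identifier, abiotic and species
#'   columns.
#' @param species character vector of species (abundance) column names.
#' @param abiotic character vector of abiotic feature column names
#'   (soil variables and `precipitation`).
#' @param validate run [validate_community_table()] (default `TRUE`).
#' @return a `community_table` (a tibble subclass).
#' @export
community_table <- function(df, species, abiotic, validate = TRUE) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(c("plot", "subplot", "year", species, abiotic), names(df))
  if (length(missing) > 0) {
    stop_validation("community table is missing column(s): %s",
                    paste(missing, collapse = ", "))
  }
  out <- structure(df,
                   species = species, abiotic = abiotic,
                   class = c("community_table", class(df)))
  if (validate) validate_community_table(out)
  out
}

#' @export
species_names <- function(table) attr(table, "species", exact = TRUE)

#' @export
abiotic_names <- function(table) attr(table, "abiotic", exact = TRUE)

#' Validate a community table
#'
#' Checks that abundances are non-negative integers, that no abiotic value is
#' missing, that soil variables are constant across years within a subplot
#' (they are measured once), and that precipitation is identical for all
#' subplots within a year.
#'
#' @param table a [community_table()].
#' @return the table, invisibly.
#' @export
validate_community_table <- function(table) {
  sp <- species_names(table)
  ab <- abiotic_names(table)
  for (s in sp) {
    v <- table[[s]]
    if (anyNA(v)) stop_validation("missing abundance values in species column '%s'", s)
    bad <- which(v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop_validation(
        "abundances must be non-negative integers; species '%s' violates this at plot %s, subplot %s, year %s",
        s, table$plot[bad[1]], table$subplot[bad[1]], table$year[bad[1]])
    }
  }
  for (a in ab) {
    if (anyNA(table[[a]])) stop_validation("missing values in abiotic column '%s'", a)
  }
  if (nrow(table) > 0) {
    soil <- setdiff(ab, "precipitation")
    key <- paste(table$plot, table$subplot, sep = "\r")
    for (a in intersect(soil, names(table))) {
      rng <- tapply(table[[a]], key, function(x) diff(range(x)))
      if (any(rng > 1e-8)) {
        bad <- names(rng)[which(rng > 1e-8)[1]]
        stop_validation(
          "soil variable '%s' is not constant across years for subplot %s (soil is measured once per subplot)",
          a, gsub("\r", "/", bad))
      }
    }
    if ("precipitation" %in% ab) {
      rng <- tapply(table$precipitation, table$year, function(x) diff(range(x)))
      if (any(rng > 1e-8)) {
        stop_validation("precipitation must be identical for all subplots within year %s",
                        names(rng)[which(rng > 1e-8)[1]])
      }
    }
    dup <- duplicated(paste(table$plot, table$subplot, table$year, sep = "\r"))
    if (any(dup)) {
      stop_validation("duplicate (plot, subplot, year) record at row %d", which(dup)[1])
    }
  }
  invisible(table)
}

#' Read a community table from CSV
#'
#' Expects a wide RFC 4180 CSV with a header: identifier columns, one column
#' per abiotic variable and one integer column per species. Abundances are
#' coerced to integer and validated.
#'
#' @param path path to the CSV file.
#' @param schema list with `species` and `abiotic` character vectors (and
#'   optionally `id`); defaults to [default_schema()]. A path to a YAML file
#'   with the same structure is also accepted.
#' @return a [community_table()].
#' @export
read_community_table <- function(path, schema = default_schema()) {
  if (is.character(schema) && length(schema) == 1) schema <- yaml::read_yaml(schema)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("plot", "subplot", "year", schema$species, schema$abiotic), names(df))
  if (length(missing) > 0) {
    stop_validation("input CSV is missing column(s): %s", paste(missing, collapse = ", "))
  }
  for (s in schema$species) {
    v <- df[[s]]
    if (nrow(df) == 0) {
      df[[s]] <- integer(0)
      next
    }
    if (anyNA(v) || !is.numeric(v) || any(v < 0) || any(v != round(v))) {
      bad <- which(is.na(v) | suppressWarnings(as.numeric(v)) < 0 |
                     suppressWarnings(as.numeric(v)) != round(suppressWarnings(as.numeric(v))))[1]
      if (is.na(bad)) bad <- 1L
      stop_validation(
        "abundance column '%s' must hold non-negative integers (violated at plot %s, subplot %s, year %s)",
        s, df$plot[bad], df$subplot[bad], df$year[bad])
    }
    df[[s]] <- as.integer(round(v))
  }
  df$plot <- as.character(df$plot)
  df$subplot <- as.character(df$subplot)
  if (nrow(df) > 0 && all(df$year == round(df$year))) df$year <- as.integer(df$year)
  community_table(df, species = schema$species, abiotic = schema$abiotic)
}

#' Write a community table to CSV
#'
#' The written file round-trips: reading it back with the same schema
#' reproduces the table field-for-field.
#'
#' @param table a [community_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path) {
  validate_community_table(table)
  readr::write_csv(tibble::as_tibble(unclass_table(table)), path, progress = FALSE)
  invisible(path)
}

unclass_table <- function(table) {
  attr(table, "species") <- NULL
  attr(table, "abiotic") <- NULL
  class(table) <- setdiff(class(table), "community_table")
  table
}

#' Subset community records while preserving the schema
#'
#' @param table a [community_table()].
#' @param idx logical or integer row index over communities.
#' @return a [community_table()] with the selected records.
#' @export
subset_communities <- function(table, idx) {
  out <- tibble::as_tibble(unclass_table(table))[idx, , drop = FALSE]
  community_table(out, species_names(table), abiotic_names(table), validate = FALSE)
}

#' Convert a community table to long format
#'
#' One row per (community, species) with an `abundance` column; the inverse
#' of [long_to_community_table()]. Offered because field data are often
#' curated in long form.
#'
#' @param table a [community_table()].
#' @return a tibble in long format.
#' @export
community_table_to_long <- function(table) {
  sp <- species_names(table)
  base <- tibble::as_tibble(unclass_table(table))[setdiff(names(table), sp)]
  out <- base[rep(seq_len(nrow(base)), length(sp)), , drop = FALSE]
  out$species <- rep(sp, each = nrow(base))
  out$abundance <- unlist(lapply(sp, function(s) table[[s]]), use.names = FALSE)
  tibble::as_tibble(out)
}

#' Convert a long-format table to a community table
#'
#' @param long tibble with identifier and abiotic columns plus `species` and
#'   `abundance`.
#' @param species optional species ordering; defaults to order of appearance.
#' @param abiotic abiotic column names present in `long`.
#' @return a [community_table()].
#' @export
long_to_community_table <- function(long, species = NULL, abiotic) {
  species <- species %||% unique(long$species)
  key_cols <- setdiff(names(long), c("species", "abundance"))
  key <- do.call(paste, c(long[key_cols], sep = "\r"))
  ukey <- !duplicated(key)
  wide <- tibble::as_tibble(long[ukey, key_cols, drop = FALSE])
  rowix <- match(key, key[ukey])
  for (s in species) {
    col <- rep(NA_integer_, nrow(wide))
    sel <- long$species == s
    col[rowix[sel]] <- as.integer(long$abundance[sel])
    wide[[s]] <- col
  }
  community_table(wide, species = species, abiotic = abiotic)
}

#' Build the stacked cross-species model frame
#'
#' Stacks the table into one row per (focal species, community). Each row
#' carries the retained abiotic features, one competitor-abundance column per
#' species (prefix `comp_`), a one-hot species-identity block (prefix `sp_`),
#' and the focal species' abundance as the target. Where the competitor and
#' focal species coincide the competitor value is set to 0, since the focal
#' abundance is the quantity being predicted.
#'
#' @param table a [community_table()].
#' @param features retained abiotic feature names (default: all abiotic
#'   columns of the table).
#' @param include_competitors add the observed competitor-abundance block
#'   (default `TRUE`); with `FALSE` the frame is abiotic-only, as used by the
#'   first stage of the two-step model.
#' @return a `model_frame` tibble with attributes `feature_cols`,
#'   `comp_cols`, `sp_cols`, `species` and `target_col`.
#' @export
build_model_frame <- function(table, features = NULL,
                              include_competitors = TRUE) {
  sp <- species_names(table)
  if (length(sp) == 0) stop_validation("species list is empty")
  features <- features %||% abiotic_names(table)
  missing <- setdiff(features, names(table))
  if (length(missing) > 0) {
    stop_validation("requested feature(s) absent from table: %s",
                    paste(missing, collapse = ", "))
  }
  n <- nrow(table)
  m <- length(sp)
  idx <- rep(seq_len(n), times = m)
  out <- tibble::as_tibble(unclass_table(table))[idx, intersect(c("plot", "subplot", "year"), names(table)), drop = FALSE]
  out$focal <- rep(sp, each = n)
  for (f in features) out[[f]] <- table[[f]][idx]

  comp_cols <- character(0)
  if (include_competitors && n > 0) {
    A <- as.matrix(tibble::as_tibble(unclass_table(table))[sp])
    storage.mode(A) <- "double"
    comp <- A[idx, , drop = FALSE]
    for (i in seq_len(m)) comp[((i - 1L) * n + 1L):(i * n), i] <- 0
    colnames(comp) <- paste0("comp_", sp)
    comp_cols <- colnames(comp)
    for (j in seq_len(m)) out[[comp_cols[j]]] <- comp[, j]
  } else if (include_competitors) {
    comp_cols <- paste0("comp_", sp)
    for (cc in comp_cols) out[[cc]] <- numeric(0)
  }

  sp_cols <- paste0("sp_", sp)
  for (i in seq_len(m)) {
    v <- numeric(n * m)
    if (n > 0) v[((i - 1L) * n + 1L):(i * n)] <- 1
    out[[sp_cols[i]]] <- v
  }
  out$abundance <- if (n > 0) as.numeric(unlist(lapply(sp, function(s) table[[s]]), use.names = FALSE)) else numeric(0)

  structure(out,
            feature_cols = features, comp_cols = comp_cols, sp_cols = sp_cols,
            species = sp, target_col = "abundance",
            class = c("model_frame", class(out)))
}

frame_predictor_cols <- function(frame) {
  c(attr(frame, "feature_cols"), attr(frame, "comp_cols"), attr(frame, "sp_cols"))
}

frame_matrix <- function(frame, cols = frame_predictor_cols(frame)) {
  X <- as.matrix(tibble::as_tibble(frame)[cols])
  storage.mode(X) <- "double"
  X
}

# Subset a model frame by row index, preserving attributes.
subset_frame <- function(frame, idx) {
  out <- tibble::as_tibble(frame)[idx, , drop = FALSE]
  structure(out,
            feature_cols = attr(frame, "feature_cols"),
            comp_cols = attr(frame, "comp_cols"),
            sp_cols = attr(frame, "sp_cols"),
            species = attr(frame, "species"),
            target_col = attr(frame, "target_col"),
            class = c("model_frame", class(out)))
}

# Replace the competitor block of a frame with a predicted abundance matrix
# (communities x species), re-applying the focal zero-out rule.
bind_competitor_predictions <- function(frame, pred_matrix) {
  sp <- attr(frame, "species")
  n <- nrow(pred_matrix)
  m <- length(sp)
  stopifnot(nrow(frame) == n * m, ncol(pred_matrix) == m)
  idx <- rep(seq_len(n), times = m)
  comp <- pred_matrix[idx, , drop = FALSE]
  for (i in seq_len(m)) comp[((i - 1L) * n + 1L):(i * n), i] <- 0
  for (j in seq_len(m)) frame[[paste0("comp_", sp[j])]] <- comp[, j]
  frame
}
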