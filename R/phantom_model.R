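# Phantom layouts: slices, organ mass fractions, TLD group placements.

#' Construct an organ fraction table
#'
#' An organ fraction table records, for one organ of one phantom, the fraction
#' `f_i` of the organ's mass contained in each physical phantom slice and the
#' number of TLD groups placed in that slice. The fractions weight per-slice
#' doses into the whole-organ dose, so they must sum to 1.
#'
#' @param phantom_id Phantom label, e.g. `"adult"` or `"pediatric_5yr"`.
#' @param organ Organ label, e.g. `"lung"` or `"thyroid"`.
#' @param slice Integer vector of 1-based physical slice indices, strictly
#'   increasing.
#' @param f Numeric vector of mass fractions in `(0, 1]`, same length as
#'   `slice`.
#' @param n_groups Integer vector of TLD group counts per slice (each >= 1).
#' @param sum_tol Absolute tolerance on `sum(f) == 1`. Defaults to 5e-3
#'   because published fraction tables are rounded to two decimals; pass
#'   `1e-9` for exact tables.
#' @return An object of class `organ_fraction_table`: a data frame with
#'   columns `slice`, `f`, `n_groups` and attributes `phantom_id`, `organ`.
#' @seealso [validate_fractions()], [phantom_layout()]
#' @export
organ_fraction_table <- function(phantom_id, organ, slice, f, n_groups,
                                 sum_tol = 5e-3) {
  stopifnot(length(slice) == length(f), length(f) == length(n_groups),
            length(slice) >= 1)
  slice <- as.integer(slice)
  n_groups <- as.integer(n_groups)
  tab <- structure(
    data.frame(slice = slice, f = as.numeric(f), n_groups = n_groups),
    phantom_id = as.character(phantom_id),
    organ = as.character(organ),
    class = c("organ_fraction_table", "data.frame")
  )
  rep <- validate_fractions(tab, sum_tol = sum_tol)
  if (!rep$pass) {
    stop("invalid fraction table for organ '", organ, "': ",
         paste(rep$messages, collapse = "; "), call. = FALSE)
  }
  tab
}

#' Validate an organ fraction table
#'
#' Checks that every fraction lies in `(0, 1]`, every group count is at least
#' one, slice indices are unique and strictly increasing, and the fractions
#' sum to one within `sum_tol`.
#'
#' @param table An [organ_fraction_table()].
#' @param sum_tol Absolute tolerance on the fraction sum (default `5e-3`,
#'   suited to tables rounded to two decimals).
#' @return A list with elements `pass` (logical), `fraction_sum`,
#'   `messages` (character vector of failures, empty when passing) and
#'   `bad_rows` (indices of offending rows).
#' @export
validate_fractions <- function(table, sum_tol = 5e-3) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  msgs <- character()
  bad <- integer()

  out_of_range <- which(!(table$f > 0 & table$f <= 1))
  if (length(out_of_range)) {
    msgs <- c(msgs, sprintf("f outside (0, 1] in row(s) %s",
                            paste(out_of_range, collapse = ", ")))
    bad <- c(bad, out_of_range)
  }
  bad_groups <- which(table$n_groups < 1)
  if (length(bad_groups)) {
    msgs <- c(msgs, sprintf("n_groups < 1 in row(s) %s",
                            paste(bad_groups, collapse = ", ")))
    bad <- c(bad, bad_groups)
  }
  if (anyDuplicated(table$slice) || is.unsorted(table$slice, strictly = TRUE)) {
    msgs <- c(msgs, "slice indices must be unique and strictly increasing")
  }
  fsum <- sum(table$f)
  if (abs(fsum - 1) > sum_tol) {
    msgs <- c(msgs, sprintf("fractions sum to %.6f, not 1 (tol %g)",
                            fsum, sum_tol))
  }
  list(pass = length(msgs) == 0L, fraction_sum = fsum,
       messages = msgs, bad_rows = sort(unique(bad)))
}

#' Construct a phantom layout
#'
#' Bundles the per-organ fraction tables of one anthropomorphic phantom with
#' its total TLD group count (the adult thorax layout used here carries 40
#' groups of three chips; the pediatric 5-year-old layout carries 36, of
#' which 4 sit in the thyroid slice).
#'
#' @param phantom_id Phantom label.
#' @param fraction_tables Named list of [organ_fraction_table()] objects, one
#'   per organ; names are the organ labels.
#' @return An object of class `phantom_layout` with fields `phantom_id`,
#'   `fraction_tables` and `total_groups`.
#' @export
phantom_layout <- function(phantom_id, fraction_tables) {
  stopifnot(is.list(fraction_tables), length(fraction_tables) >= 1)
  if (is.null(names(fraction_tables)) || any(names(fraction_tables) == "")) {
    names(fraction_tables) <- vapply(fraction_tables, attr, "", "organ")
  }
  total <- sum(vapply(fraction_tables, function(t) sum(t$n_groups), 0))
  structure(
    list(phantom_id = as.character(phantom_id),
         fraction_tables = fraction_tables,
         total_groups = as.integer(total)),
    class = "phantom_layout"
  )
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat("Phantom layout:", x$phantom_id, "\n")
  cat("  organs:", paste(names(x$fraction_tables), collapse = ", "), "\n")
  cat("  total TLD groups:", x$total_groups, "\n")
  for (org in names(x$fraction_tables)) {
    t <- x$fraction_tables[[org]]
    cat(sprintf("  %s: %d slice(s), sum(f) = %.4f, %d group(s)\n",
                org, nrow(t), sum(t$f), sum(t$n_groups)))
  }
  invisible(x)
}

#' Load a phantom layout from JSON
#'
#' Reads the layout dialect
#' `{"phantom_id": ..., "organs": [{"organ", "rows": [{"slice", "f",
#' "n_groups"}]}]}` and validates every fraction table. Fixture layouts for
#' the adult RANDO and pediatric CIRS ATOM phantoms ship with the package
#' under `inst/extdata`.
#'
#' @param path Path to a layout JSON file.
#' @param sum_tol Fraction-sum tolerance forwarded to
#'   [organ_fraction_table()] (default `5e-3` for rounded published tables).
#' @return A validated [phantom_layout()].
#' @examples
#' layout <- load_layout(ctdose_extdata("adult_rando.json"))
#' layout$total_groups  # 40
#' @export
load_layout <- function(path, sum_tol = 5e-3) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse layout JSON '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  for (field in c("phantom_id", "organs")) {
    if (is.null(doc[[field]])) {
      stop("layout file '", path, "' is missing field '", field, "'",
           call. = FALSE)
    }
  }
  tables <- lapply(doc$organs, function(o) {
    if (is.null(o$organ) || is.null(o$rows)) {
      stop("layout organ entry missing 'organ' or 'rows'", call. = FALSE)
    }
    rows <- o$rows
    get_col <- function(name) {
      vals <- lapply(rows, `[[`, name)
      if (any(vapply(vals, is.null, TRUE))) {
        stop("layout row in organ '", o$organ, "' is missing field '", name,
             "'", call. = FALSE)
      }
      unlist(vals)
    }
    organ_fraction_table(doc$phantom_id, o$organ,
                         slice = get_col("slice"), f = get_col("f"),
                         n_groups = get_col("n_groups"), sum_tol = sum_tol)
  })
  names(tables) <- vapply(doc$organs, `[[`, "", "organ")
  phantom_layout(doc$phantom_id, tables)
}

#' Write a phantom layout to JSON
#'
#' Inverse of [load_layout()]; a load/write/load round trip is lossless.
#'
#' @param layout A [phantom_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "phantom_layout"))
  doc <- list(
    phantom_id = layout$phantom_id,
    organs = lapply(names(layout$fraction_tables), function(org) {
      t <- layout$fraction_tables[[org]]
      list(organ = org,
           rows = lapply(seq_len(nrow(t)), function(i) {
             list(slice = t$slice[i], f = t$f[i], n_groups = t$n_groups[i])
           }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path (or a vector of file names).
#' @export
ctdose_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ctdose")))
  }
  p <- system.file("extdata", file, package = "ctdose")
  if (p == "") stop("no packaged fixture named '", file, "'", call. = FALSE)
  p
}
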