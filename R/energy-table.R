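# Keyed container for single-point electronic energies:
# (species, method, basis) -> HF + correlation components.
# Energies are held internally in hartree; report-facing output is kcal/mol.

#' Correlation-consistent basis levels
#'
#' Maps aug-cc-pVXZ labels to cardinal numbers X (2 = double-zeta,
#' 3 = triple-zeta, 4 = quadruple-zeta) and back.
#'
#' @param label basis label, e.g. `"aug-cc-pVTZ"`.
#' @param cardinal integer cardinal number.
#' @return `basis_cardinal()` the cardinal; `basis_label()` the label.
#' @export
basis_cardinal <- function(label) {
  m <- regmatches(label, regexec("^aug-cc-pV([DTQ56])Z$", label))[[1]]
  if (length(m) != 2L) {
    stop("cannot resolve basis label to a cardinal: ", label, call. = FALSE)
  }
  unname(c(D = 2L, T = 3L, Q = 4L, `5` = 5L, `6` = 6L)[m[2]])
}

#' @rdname basis_cardinal
#' @export
basis_label <- function(cardinal) {
  letter <- c(`2` = "D", `3` = "T", `4` = "Q", `5` = "5", `6` = "6")[
    as.character(cardinal)]
  if (is.na(letter)) stop("unsupported cardinal: ", cardinal, call. = FALSE)
  paste0("aug-cc-pV", letter, "Z")
}

#' HF + correlation energy components
#'
#' The mean-field (Hartree-Fock) and correlation components of an electronic
#' energy, which converge to the basis-set limit at different rates and are
#' therefore extrapolated separately.
#'
#' @param hf,corr [quantity()] energies in the same unit.
#' @return A `component_energy` list with `hf`, `corr` and `total = hf + corr`.
#' @export
component_energy <- function(hf, corr) {
  if (!is_quantity(hf) || !is_quantity(corr)) {
    stop("`hf` and `corr` must be quantities", call. = FALSE)
  }
  structure(list(hf = hf, corr = corr, total = hf + corr),
            class = "component_energy")
}

#' @export
print.component_energy <- function(x, ...) {
  cat("HF   ", format(x$hf), "\ncorr ", format(x$corr),
      "\ntotal", format(x$total), "\n")
  invisible(x)
}

.et_key <- function(df) {
  paste(df$complex_id, df$oxidation_state, df$method, df$cardinal, sep = "\r")
}

#' Build an energy table
#'
#' @param df data frame with columns `complex_id`, `oxidation_state`
#'   (II/III), `multiplicity`, `method` (e.g. "MP2", "CCSD(T)"),
#'   `cardinal` (or `basis_label`), `e_hf`, `e_corr` in hartree.
#' @return An `energy_table` (a validated data frame); the key
#'   (species, method, basis) must be unique.
#' @export
energy_table <- function(df) {
  needed <- c("complex_id", "oxidation_state", "multiplicity", "method",
              "e_hf", "e_corr")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("energy table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"cardinal" %in% names(df)) {
    if (!"basis_label" %in% names(df)) {
      stop("energy table needs a `cardinal` or `basis_label` column",
           call. = FALSE)
    }
    df$cardinal <- vapply(df$basis_label, basis_cardinal, integer(1))
  }
  if (!"basis_label" %in% names(df)) {
    df$basis_label <- vapply(df$cardinal, basis_label, character(1))
  }
  bad_state <- !df$oxidation_state %in% c("II", "III")
  if (any(bad_state)) {
    stop("unknown oxidation state in rows: ",
         paste(which(bad_state), collapse = ", "), call. = FALSE)
  }
  key <- .et_key(df)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (species, method, basis) keys in rows: ",
         paste(which(dup), collapse = ", "), " [",
         paste(unique(gsub("\r", "/", key[dup])), collapse = "; "), "]",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("energy_table", "data.frame")
  df
}

#' Look up one energy record
#'
#' Absent keys fail loudly, naming the missing (species, method, basis).
#'
#' @param tab an [energy_table()].
#' @param complex_id,oxidation_state,method,cardinal the record key.
#' @return A [component_energy()] in hartree.
#' @export
lookup_energy <- function(tab, complex_id, oxidation_state, method, cardinal) {
  stopifnot(inherits(tab, "energy_table"))
  hit <- tab$complex_id == complex_id &
    tab$oxidation_state == oxidation_state &
    tab$method == method & tab$cardinal == cardinal
  if (!any(hit)) {
    stop("no energy record for (", complex_id, " Fe(", oxidation_state, "), ",
         method, ", ", basis_label(cardinal), ")", call. = FALSE)
  }
  row <- tab[which(hit)[1], ]
  component_energy(quantity(row$e_hf, "hartree"), quantity(row$e_corr, "hartree"))
}

#' Read / write the delimited energy-table format
#'
#' Comma-separated UTF-8 with a header row and columns `complex_id`,
#' `oxidation_state`, `multiplicity`, `method`, `basis_label`, `e_hf`,
#' `e_corr`, `unit` (`hartree` or `kcal_per_mol`).  Values are converted to
#' hartree on read; full precision, no locale formatting on write.
#'
#' @param path file path.
#' @return `read_energy_table()` an [energy_table()];
#'   `write_energy_table()` invisibly, the path.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("complex_id", "oxidation_state", "multiplicity", "method",
              "basis_label", "e_hf", "e_corr", "unit")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$unit %in% c("hartree", "kcal_per_mol"))
  if (length(bad)) {
    stop(path, ": unknown unit on line(s) ",
         paste(bad + 1L, collapse = ", "), " (+1 for header): ",
         paste(unique(df$unit[bad]), collapse = ", "), call. = FALSE)
  }
  to_h <- ifelse(df$unit == "hartree", 1, 1 / HARTREE_TO_KCAL)
  df$e_hf <- df$e_hf * to_h
  df$e_corr <- df$e_corr * to_h
  df$unit <- NULL
  tryCatch(energy_table(df), error = function(e) {
    stop(path, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' @rdname read_energy_table
#' @param tab an [energy_table()] (stored in hartree).
#' @export
write_energy_table <- function(tab, path) {
  stopifnot(inherits(tab, "energy_table"))
  out <- as.data.frame(tab)[, c("complex_id", "oxidation_state",
                                "multiplicity", "method", "basis_label",
                                "e_hf", "e_corr")]
  out$unit <- "hartree"
  utils::write.csv(format(out, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
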