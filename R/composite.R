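# Composite CCSD(T)/CBS reference assembly:
# E[CCSD(T)/CBS] ~= E[MP2/CBS] + (E[CCSD(T)] - E[MP2]) at a common small
# basis (double-zeta here).  The correction is weakly basis-dependent, which
# is what makes the composite accurate at double-zeta cost.

#' A coupled-cluster correction at a stated basis
#'
#' @param value a [quantity()]: `E_CCSD(T) - E_MP2` at `basis`.
#' @param basis cardinal number of the common basis (2 in this workflow).
#' @return A `composite_correction` list.
#' @export
composite_correction <- function(value, basis = 2L) {
  if (!is_quantity(value)) stop("`value` must be a quantity", call. = FALSE)
  structure(list(value = value, basis = as.integer(basis)),
            class = "composite_correction")
}

#' Assemble a composite CCSD(T)/CBS energy
#'
#' @param mp2_cbs a [quantity()]: the MP2/CBS value.
#' @param correction a [composite_correction()] in the same unit.
#' @return A `quantity`: `mp2_cbs + correction$value`.
#' @examples
#' composite_cbs(quantity(-602.8540, "kcal_per_mol"),
#'               composite_correction(quantity(9.0487, "kcal_per_mol")))
#' @export
composite_cbs <- function(mp2_cbs, correction) {
  stopifnot(inherits(correction, "composite_correction"))
  if (!is_quantity(mp2_cbs)) stop("`mp2_cbs` must be a quantity", call. = FALSE)
  mp2_cbs + correction$value
}

#' Build the CCSD(T)/CBS reference table for all couples in an energy table
#'
#' For every complex present, the MP2 energy of each oxidation state is
#' extrapolated to the CBS limit with the chosen scheme, the double-zeta
#' CCSD(T) - MP2 correction is added per species, and the reduction energy
#' dE_elec = E(II) - E(III) is formed.  Report order follows the canonical
#' 12-complex order; unknown complexes are appended alphabetically.
#'
#' @param tab an [energy_table()] holding MP2 records at the scheme's
#'   cardinals and MP2 + CCSD(T) records at `correction_basis`, for both
#'   oxidation states of each complex.
#' @param scheme `"scheme2"` (the default used for references) or
#'   `"scheme1"`.
#' @param correction_basis cardinal of the coupled-cluster correction
#'   (default 2).
#' @param params a [cbs_params()].
#' @return A data frame of class `reference_table` with columns
#'   `complex_id`, `delta_e_kcal` (CCSD(T)/CBS), `mp2_cbs_kcal`,
#'   `correction_kcal`, `scheme`, `correction_basis`.
#' @export
build_reference_table <- function(tab, scheme = c("scheme2", "scheme1"),
                                  correction_basis = 2L,
                                  params = cbs_params()) {
  stopifnot(inherits(tab, "energy_table"))
  scheme <- match.arg(scheme)
  ids <- unique(tab$complex_id)
  canon <- iron_complexes()$complex_id
  ids <- c(canon[canon %in% ids], sort(setdiff(ids, canon)))

  one_species <- function(id, state) {
    cbs <- extrapolate_species(tab, id, state, scheme = scheme,
                               params = params)
    mp2_dz <- lookup_energy(tab, id, state, "MP2", correction_basis)
    cc_dz <- lookup_energy(tab, id, state, "CCSD(T)", correction_basis)
    corr <- composite_correction(cc_dz$total - mp2_dz$total, correction_basis)
    list(mp2_cbs = cbs$cbs_total, composite = composite_cbs(cbs$cbs_total, corr),
         correction = corr$value)
  }

  rows <- lapply(ids, function(id) {
    red <- one_species(id, "II")
    ox <- one_species(id, "III")
    kc <- function(q) qty_value(convert(q, "kcal_per_mol"))
    data.frame(
      complex_id = id,
      delta_e_kcal = kc(delta_e_redox(red$composite, ox$composite)),
      mp2_cbs_kcal = kc(delta_e_redox(red$mp2_cbs, ox$mp2_cbs)),
      correction_kcal = kc(red$correction - ox$correction),
      scheme = scheme,
      correction_basis = as.integer(correction_basis),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Read / write a reference table
#'
#' Comma-separated with columns `complex_id`, `delta_e_kcal`, `scheme`,
#' `correction_basis` (plus any extra numeric columns present).
#'
#' @param x a `reference_table` data frame.
#' @param path file path.
#' @return `read_reference_table()` a data frame; `write_reference_table()`
#'   invisibly, the path.
#' @export
write_reference_table <- function(x, path) {
  utils::write.csv(format(as.data.frame(x), digits = 17,
                          scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("complex_id", "delta_e_kcal")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}
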