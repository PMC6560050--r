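# Unit-tagged energies.  Every number that crosses a module boundary carries
# its unit; mixed-unit arithmetic is an error, not a silent bug.

#' @keywords internal
HARTREE_TO_KCAL <- 627.509474

#' @keywords internal
EV_TO_KCAL <- 23.060548

# volt is treated as eV per single electron transferred; multi-electron
# conversion goes through volts_to_kcal() where the electron count is explicit.
.qty_units <- c("hartree", "kcal_per_mol", "eV", "volt")

# conversion factors to the canonical internal unit (hartree)
.to_hartree <- c(
  hartree      = 1,
  kcal_per_mol = 1 / HARTREE_TO_KCAL,
  eV           = EV_TO_KCAL / HARTREE_TO_KCAL,
  volt         = EV_TO_KCAL / HARTREE_TO_KCAL
)

#' Create a unit-tagged energy quantity
#'
#' A `quantity` is a numeric vector carrying an energy (or potential) unit.
#' Addition, subtraction and comparison between quantities require identical
#' units; use [convert()] to change units explicitly.  The `volt` unit follows
#' the single-electron convention (1 V across one electron equals 1 eV); for
#' multi-electron transfers use [volts_to_kcal()].
#'
#' @param value numeric vector.
#' @param unit one of `"hartree"`, `"kcal_per_mol"`, `"eV"`, `"volt"`.
#' @return An object of class `quantity`.
#' @examples
#' e <- quantity(-1.5, "hartree")
#' convert(e, "kcal_per_mol")
#' @export
quantity <- function(value, unit) {
  if (!is.numeric(value)) stop("`value` must be numeric", call. = FALSE)
  unit <- match.arg(unit, .qty_units)
  structure(as.numeric(value), unit = unit, class = "quantity")
}

#' Test for / access a quantity
#' @param x object to test or query.
#' @return `is_quantity()` a logical; `qty_unit()` the unit string;
#'   `qty_value()` the bare numeric vector.
#' @export
is_quantity <- function(x) inherits(x, "quantity")

#' @rdname is_quantity
#' @export
qty_unit <- function(x) {
  if (!is_quantity(x)) stop("not a quantity", call. = FALSE)
  attr(x, "unit")
}

#' @rdname is_quantity
#' @export
qty_value <- function(x) {
  if (!is_quantity(x)) stop("not a quantity", call. = FALSE)
  as.numeric(unclass(x))
}

#' Convert a quantity to another unit
#'
#' Conversion goes through hartree with the constants 627.509474 kcal/mol per
#' hartree and 23.060548 kcal/mol per eV, so chained conversions are
#' path-independent to floating-point precision.
#'
#' @param q a [quantity()].
#' @param to target unit.
#' @return A `quantity` in the target unit.
#' @export
convert <- function(q, to) {
  if (!is_quantity(q)) stop("`q` must be a quantity", call. = FALSE)
  if (length(to) != 1L || !to %in% .qty_units) {
    stop("unknown unit: ", paste(to, collapse = ", "), call. = FALSE)
  }
  from <- qty_unit(q)
  if (from == to) return(q)
  quantity(qty_value(q) * .to_hartree[[from]] / .to_hartree[[to]], to)
}

.same_unit <- function(e1, e2, op) {
  u1 <- qty_unit(e1); u2 <- qty_unit(e2)
  if (u1 != u2) {
    stop("unit mismatch in `", op, "`: ", u1, " vs ", u2,
         " (convert() explicitly)", call. = FALSE)
  }
  u1
}

#' @export
Ops.quantity <- function(e1, e2) {
  if (missing(e2)) {          # unary + / -
    return(quantity(get(.Generic)(qty_value(e1)), qty_unit(e1)))
  }
  both <- is_quantity(e1) && is_quantity(e2)
  if (.Generic %in% c("+", "-")) {
    if (!both) stop("cannot ", .Generic, " a quantity and a bare number",
                    call. = FALSE)
    u <- .same_unit(e1, e2, .Generic)
    return(quantity(get(.Generic)(qty_value(e1), qty_value(e2)), u))
  }
  if (.Generic %in% c("==", "!=", "<", ">", "<=", ">=")) {
    if (!both) stop("cannot compare a quantity with a bare number",
                    call. = FALSE)
    u <- .same_unit(e1, e2, .Generic)
    return(get(.Generic)(qty_value(e1), qty_value(e2)))
  }
  if (.Generic %in% c("*", "/")) {
    if (both) stop("product of two quantities is not an energy", call. = FALSE)
    if (is_quantity(e1)) {
      return(quantity(get(.Generic)(qty_value(e1), e2), qty_unit(e1)))
    }
    if (.Generic == "/") stop("cannot divide a scalar by a quantity",
                              call. = FALSE)
    return(quantity(e1 * qty_value(e2), qty_unit(e2)))
  }
  stop("operation `", .Generic, "` not defined for quantities", call. = FALSE)
}

#' @export
print.quantity <- function(x, digits = 6, ...) {
  cat(format(qty_value(x), digits = digits), qty_unit(x), "\n")
  invisible(x)
}

#' @export
format.quantity <- function(x, ...) {
  paste(format(qty_value(x), ...), qty_unit(x))
}

#' @export
abs.quantity <- function(x) quantity(abs(qty_value(x)), qty_unit(x))

#' Convert a potential to an energy over n transferred electrons
#'
#' An error of `potential` volts across `electrons` electrons corresponds to
#' `potential * electrons * 23.060548` kcal/mol.  The accuracy-group
#' boundaries (0.1 V and 0.2 V per one-electron transfer, i.e. 2.31 and
#' 4.62 kcal/mol at 2 decimals) come from this conversion.
#'
#' @param potential a `quantity` in volt (or a bare number, taken as volt).
#' @param electrons positive integer count of transferred electrons.
#' @return A `quantity` in kcal/mol.
#' @examples
#' volts_to_kcal(quantity(0.1, "volt"), 1) # ~2.31 kcal/mol
#' @export
volts_to_kcal <- function(potential, electrons = 1L) {
  if (!is.numeric(electrons) || length(electrons) != 1L || electrons < 1 ||
      electrons != as.integer(electrons)) {
    stop("`electrons` must be a positive integer", call. = FALSE)
  }
  v <- if (is_quantity(potential)) {
    if (qty_unit(potential) != "volt") stop("`potential` must be in volt",
                                            call. = FALSE)
    qty_value(potential)
  } else {
    as.numeric(potential)
  }
  quantity(v * electrons * EV_TO_KCAL, "kcal_per_mol")
}
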