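## Cromer-Mann atomic form factors and the implicit-solvent correction.

.ffCache <- new.env(parent = emptyenv())

#' Load the shipped Cromer-Mann form-factor table
#'
#' Four-Gaussian-plus-constant coefficients per element (q in Angstrom^-1,
#' b_k in Angstrom^2) with displaced solvent volumes (nm^3). The table is
#' read once per session and cached.
#'
#' @param path optional path to an alternative table with the same columns.
#' @return a [FormFactorTable-class]
#' @examples
#' tab <- cromerMannTable()
#' atomicFormFactor("C", 0, tab)  # close to carbon's atomic number
#' @export
cromerMannTable <- function(path = NULL) {
    if (is.null(path)) {
        if (!is.null(.ffCache$default)) return(.ffCache$default)
        path <- system.file("extdata", "cromer_mann.tsv",
                            package = "glycoSAXS", mustWork = TRUE)
        tab <- new("FormFactorTable", coefficients = utils::read.table(
            path, header = TRUE, sep = "\t", comment.char = "#",
            stringsAsFactors = FALSE))
        .ffCache$default <- tab
        return(tab)
    }
    new("FormFactorTable", coefficients = utils::read.table(
        path, header = TRUE, sep = "\t", comment.char = "#",
        stringsAsFactors = FALSE))
}

.ffRow <- function(element, table) {
    co <- table@coefficients
    i <- match(element, co$element)
    if (anyNA(i))
        stop("unknown element '", element[which(is.na(i))[1]],
             "' in form-factor table (available: ",
             paste(co$element, collapse = ", "), ")")
    co[i, , drop = FALSE]
}

#' Atomic X-ray form factor f(q)
#'
#' Evaluates f(q) = c + sum_k a_k exp(-b_k (q / 4 pi)^2) from the
#' Cromer-Mann coefficients. At q = 0 this equals c + sum a_k, which is the
#' element's electron count to within the parametrisation error.
#'
#' @param element element symbol present in `table`.
#' @param q momentum transfer values, Angstrom^-1 (vectorised).
#' @param table a [FormFactorTable-class]; default the shipped table.
#' @return numeric vector of f(q), dimensionless (electrons).
#' @export
atomicFormFactor <- function(element, q, table = cromerMannTable()) {
    stopifnot(all(q >= 0))
    r <- .ffRow(element, table)
    s2 <- (q / (4 * pi))^2
    f <- rep(r$c, length(q))
    for (k in 1:4)
        f <- f + r[[paste0("a", k)]] * exp(-r[[paste0("b", k)]] * s2)
    f
}

#' Effective (solvent-corrected) form factor
#'
#' In `vacuum` mode returns the plain atomic form factor. In
#' `excluded_volume` mode subtracts a Gaussian dummy atom representing the
#' solvent the atom displaces:
#' f_eff(q) = f(q) - rho_s V exp(-q^2 V^(2/3) / (4 pi)),
#' with rho_s in e/nm^3, V in nm^3 and q converted to nm^-1 inside the
#' exponential so units are consistent. For hydrogen, whose displaced
#' volume exceeds its electron count divided by the water density, f_eff(0)
#' is negative; this is expected.
#'
#' @param element element symbol.
#' @param q momentum transfer, Angstrom^-1 (vectorised).
#' @param table a [FormFactorTable-class].
#' @param solvent a [SolventModel-class].
#' @return numeric vector, dimensionless (electrons).
#' @export
effectiveFormFactor <- function(element, q, table = cromerMannTable(),
                                solvent = solventModel("vacuum")) {
    f <- atomicFormFactor(element, q, table)
    if (solvent@mode == "vacuum" || solvent@electronDensity == 0)
        return(f)
    r <- .ffRow(element, table)
    V <- r$volume_nm3
    if (is.na(V))
        stop("no displaced volume for element '", element,
             "' (required in excluded_volume mode)")
    q_nm <- q * 10  # A^-1 -> nm^-1
    f - solvent@electronDensity * V * exp(-q_nm^2 * V^(2 / 3) / (4 * pi))
}

## Matrix of effective form factors: rows = atoms, cols = q values.
.formFactorMatrix <- function(elements, q, table, solvent) {
    uniq <- unique(elements)
    per_elem <- vapply(uniq, function(e)
        effectiveFormFactor(e, q, table, solvent), numeric(length(q)))
    per_elem <- matrix(per_elem, nrow = length(q), ncol = length(uniq),
                       dimnames = list(NULL, uniq))
    t(per_elem)[match(elements, uniq), , drop = FALSE]
}

#' Electron counts for a set of elements
#'
#' Atomic numbers from the form-factor table; used for electron-weighted
#' radius of gyration.
#'
#' @param elements character vector of element symbols.
#' @param table a [FormFactorTable-class].
#' @return numeric vector of electron counts.
#' @export
electronCounts <- function(elements, table = cromerMannTable()) {
    .ffRow(elements, table)$z
}
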