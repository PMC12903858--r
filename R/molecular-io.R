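## Readers/writers for PDB, GRO and 2-3 column ASCII scattering curves.
## Internal lengths are nm: PDB coordinates (Angstrom) are divided by 10 on
## input, GRO files are already in nm. q is Angstrom^-1 at all interfaces.

.ORGANIC_ELEMENTS <- c("C", "H", "N", "O", "P", "S")

.normElement <- function(x) {
    x <- trimws(x)
    ifelse(nchar(x) == 0, "",
           paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2))))
}

#' Infer an element symbol from a PDB/GRO atom name
#'
#' The element column wins when present. Otherwise the leading letters of the
#' atom name are used; a two-letter symbol is preferred when it names a known
#' element whose first letter is not itself one of the organic elements
#' C/H/N/O/P/S (so `"CA"` in a sugar resolves to carbon but `"FE"` to iron).
#' Unknown names are an error unless `overrides` maps them.
#'
#' @param name atom name(s) as written in the file.
#' @param known character vector of recognized element symbols.
#' @param overrides named character vector mapping atom names to elements.
#' @return character vector of element symbols.
#' @keywords internal
.inferElement <- function(name, known, overrides = character()) {
    vapply(name, function(nm) {
        nm0 <- trimws(nm)
        if (nm0 %in% names(overrides)) return(overrides[[nm0]])
        letters_only <- gsub("[^A-Za-z]", "", nm0)
        if (nchar(letters_only) == 0L)
            stop("cannot infer element from atom name '", nm, "'")
        one <- .normElement(substr(letters_only, 1, 1))
        two <- if (nchar(letters_only) >= 2L)
            .normElement(substr(letters_only, 1, 2)) else ""
        if (nzchar(two) && two %in% known && !(one %in% .ORGANIC_ELEMENTS))
            return(two)
        if (one %in% known) return(one)
        if (nzchar(two) && two %in% known) return(two)
        stop("unknown element for atom name '", nm,
             "'; supply element_overrides (known: ",
             paste(known, collapse = ", "), ")")
    }, character(1), USE.NAMES = FALSE)
}

.parsePdbAtomLines <- function(lines, line_numbers, overrides, known) {
    num <- function(s, what, ln) {
        v <- suppressWarnings(as.numeric(s))
        bad <- which(is.na(v))
        if (length(bad))
            stop("PDB format error at line ", ln[bad[1]],
                 ": unparseable ", what, " field '", trimws(s[bad[1]]), "'")
        v
    }
    name <- substr(lines, 13, 16)
    res_name <- trimws(substr(lines, 18, 20))
    res_id <- suppressWarnings(as.integer(trimws(substr(lines, 23, 26))))
    res_id[is.na(res_id)] <- 1L
    x <- num(substr(lines, 31, 38), "x", line_numbers)
    y <- num(substr(lines, 39, 46), "y", line_numbers)
    z <- num(substr(lines, 47, 54), "z", line_numbers)
    elem_col <- .normElement(substr(lines, 77, 78))
    element <- ifelse(nzchar(elem_col), elem_col,
                      .inferElement(name, known, overrides))
    bad <- which(!element %in% known & !element %in% names(overrides))
    if (length(bad))
        stop("unknown element '", element[bad[1]], "' at line ",
             line_numbers[bad[1]], "; supply element_overrides")
    list(atoms = data.frame(name = trimws(name), element = element,
                            mass = .massForElement(element),
                            residue_id = res_id, residue_name = res_name,
                            stringsAsFactors = FALSE),
         xyz = matrix(c(x, y, z), ncol = 3) / 10)  # Angstrom -> nm
}

## Split a PDB file into per-model blocks of ATOM/HETATM line indices.
.pdbModelBlocks <- function(lines) {
    is_atom <- grepl("^(ATOM  |HETATM)", lines)
    model_starts <- grep("^MODEL", lines)
    if (length(model_starts) == 0L)
        return(list(which(is_atom)))
    model_ends <- grep("^(ENDMDL|END$|END )", lines)
    lapply(seq_along(model_starts), function(k) {
        lo <- model_starts[k]
        hi <- model_ends[model_ends > lo]
        hi <- if (length(hi)) hi[1] else length(lines)
        idx <- which(is_atom)
        idx[idx > lo & idx < hi + 1]
    })
}

.readGroBlocks <- function(lines) {
    blocks <- list()
    i <- 1L
    while (i <= length(lines)) {
        if (!nzchar(trimws(lines[i])) && i == length(lines)) break
        if (i + 1L > length(lines))
            stop("GRO format error at line ", i, ": truncated header")
        n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
        if (is.na(n) || n <= 0L)
            stop("GRO format error at line ", i + 1L,
                 ": expected atom count, got '", trimws(lines[i + 1L]), "'")
        atom_lines <- (i + 2L):(i + 1L + n)
        if (max(atom_lines) > length(lines))
            stop("GRO format error: frame starting at line ", i,
                 " declares ", n, " atoms but file ends early")
        blocks[[length(blocks) + 1L]] <-
            list(lines = lines[atom_lines], line_numbers = atom_lines)
        i <- i + n + 3L  # title, count, atoms, box line
    }
    if (length(blocks) == 0L) stop("empty input: no GRO frames found")
    blocks
}

.parseGroAtomLines <- function(lines, line_numbers, overrides, known) {
    num <- function(s, what, ln) {
        v <- suppressWarnings(as.numeric(s))
        bad <- which(is.na(v))
        if (length(bad))
            stop("GRO format error at line ", ln[bad[1]],
                 ": unparseable ", what, " field '", trimws(s[bad[1]]), "'")
        v
    }
    res_id <- suppressWarnings(as.integer(trimws(substr(lines, 1, 5))))
    res_id[is.na(res_id)] <- 1L
    res_name <- trimws(substr(lines, 6, 10))
    name <- trimws(substr(lines, 11, 15))
    x <- num(substr(lines, 21, 28), "x", line_numbers)
    y <- num(substr(lines, 29, 36), "y", line_numbers)
    z <- num(substr(lines, 37, 44), "z", line_numbers)
    element <- .inferElement(name, known, overrides)
    list(atoms = data.frame(name = name, element = element,
                            mass = .massForElement(element),
                            residue_id = res_id, residue_name = res_name,
                            stringsAsFactors = FALSE),
         xyz = matrix(c(x, y, z), ncol = 3))  # already nm
}

#' Read a molecular structure from PDB or GRO
#'
#' Coordinates are converted to nm internally (PDB files are Angstrom, GRO
#' files nm). When a PDB element column is blank the element is inferred from
#' the atom name (see [.inferElement()]); for multi-model files only the
#' first model is returned (use [readTrajectory()] for all of them).
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; inferred from the file extension when
#'   omitted.
#' @param element_overrides named character vector mapping atom names to
#'   element symbols, for names the inference rule cannot resolve.
#' @return a [MolecularModel-class]
#' @export
readStructure <- function(path, format = c("auto", "pdb", "gro"),
                          element_overrides = character()) {
    format <- match.arg(format)
    if (format == "auto") format <- .guessFormat(path)
    lines <- readLines(path, warn = FALSE)
    known <- cromerMannTable()@coefficients$element
    if (format == "pdb") {
        idx <- .pdbModelBlocks(lines)[[1]]
        if (length(idx) == 0L)
            stop("empty input: no ATOM/HETATM records in ", path)
        p <- .parsePdbAtomLines(lines[idx], idx, element_overrides, known)
    } else {
        blk <- .readGroBlocks(lines)[[1]]
        p <- .parseGroAtomLines(blk$lines, blk$line_numbers,
                                element_overrides, known)
    }
    new("MolecularModel", atoms = p$atoms, coordinates = p$xyz)
}

.guessFormat <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("pdb", "ent")) return("pdb")
    if (ext == "gro") return("gro")
    stop("cannot infer format from extension '", ext,
         "'; pass format = 'pdb' or 'gro'")
}

#' Read a trajectory from a multi-model PDB or concatenated GRO series
#'
#' @param frames_path path to the multi-model PDB or concatenated GRO file.
#' @param frame_time_step time between frames, ns (PDB/GRO files carry no
#'   reliable time metadata, so this is user-supplied).
#' @param topology_path optional separate structure file supplying the
#'   topology; default: the first frame of `frames_path`.
#' @param format,element_overrides as in [readStructure()].
#' @return a [TrajectoryFrames-class]
#' @export
readTrajectory <- function(frames_path, frame_time_step,
                           topology_path = NULL,
                           format = c("auto", "pdb", "gro"),
                           element_overrides = character()) {
    format <- match.arg(format)
    if (format == "auto") format <- .guessFormat(frames_path)
    lines <- readLines(frames_path, warn = FALSE)
    known <- cromerMannTable()@coefficients$element
    if (format == "pdb") {
        blocks <- .pdbModelBlocks(lines)
        parsed <- lapply(blocks, function(idx)
            .parsePdbAtomLines(lines[idx], idx, element_overrides, known))
    } else {
        blocks <- .readGroBlocks(lines)
        parsed <- lapply(blocks, function(b)
            .parseGroAtomLines(b$lines, b$line_numbers,
                               element_overrides, known))
    }
    if (length(parsed) == 0L || nrow(parsed[[1]]$atoms) == 0L)
        stop("empty input: no frames found in ", frames_path)
    model <- if (!is.null(topology_path))
        readStructure(topology_path, element_overrides = element_overrides)
    else
        new("MolecularModel", atoms = parsed[[1]]$atoms,
            coordinates = parsed[[1]]$xyz)
    n <- nAtoms(model)
    counts <- vapply(parsed, function(p) nrow(p$atoms), integer(1))
    bad <- which(counts != n)
    if (length(bad))
        stop("structural error in frame ", bad[1], ": has ", counts[bad[1]],
             " atoms, expected ", n)
    trajectoryFrames(model, lapply(parsed, `[[`, "xyz"), frame_time_step)
}

#' Read a scattering curve from whitespace-delimited ASCII
#'
#' Expects columns q (Angstrom^-1), I and optionally sigma; lines starting
#' with `#` are ignored. Rows are sorted by q; duplicate q values are
#' rejected.
#'
#' @param path file path.
#' @return a [ScatteringCurve-class]
#' @export
readScatteringCurve <- function(path) {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    if (length(keep) == 0L) stop("empty input: no data rows in ", path)
    fields <- strsplit(trimws(lines[keep]), "\\s+")
    ncol <- unique(lengths(fields))
    if (length(ncol) != 1L || !ncol %in% c(2L, 3L))
        stop("parse error in ", path,
             ": expected uniform 2 or 3 columns, found row with ",
             setdiff(lengths(fields), c(2L, 3L))[1] , " fields at line ",
             keep[which(!lengths(fields) %in% c(2L, 3L))[1]])
    vals <- suppressWarnings(vapply(fields, as.numeric, numeric(ncol)))
    bad <- which(colSums(is.na(vals)) > 0)
    if (length(bad))
        stop("parse error at line ", keep[bad[1]], " of ", path,
             ": non-numeric field")
    q <- vals[1, ]; i <- vals[2, ]
    s <- if (ncol == 3L) vals[3, ] else NULL
    ord <- order(q)
    if (anyDuplicated(q))
        stop("validation error: duplicate q value ",
             q[duplicated(q)][1], " in ", path)
    scatteringCurve(q[ord], i[ord], if (is.null(s)) NULL else s[ord])
}

#' Write a scattering curve as ASCII
#'
#' Writes 2 or 3 whitespace-delimited columns (q, I\[, sigma\]) at 6
#' significant digits so that read(write(curve)) round-trips.
#'
#' @param curve a [ScatteringCurve-class].
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
writeScatteringCurve <- function(curve, path) {
    stopifnot(is(curve, "ScatteringCurve"))
    fmt <- function(v) formatC(v, digits = 6, format = "g")
    cols <- list(fmt(curve@q), fmt(curve@intensity))
    if (hasSigma(curve)) cols <- c(cols, list(fmt(curve@sigma)))
    lines <- do.call(paste, cols)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# q[A^-1] I [sigma]", lines), con)
    invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' Used by the synthetic generator to emit regression fixtures; coordinates
#' are converted nm -> Angstrom.
#'
#' @param traj a [TrajectoryFrames-class].
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
writeMultiModelPdb <- function(traj, path) {
    stopifnot(is(traj, "TrajectoryFrames"))
    a <- atoms(traj)
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_len(nFrames(traj))) {
        writeLines(sprintf("MODEL     %4d", k), con)
        xyz <- frameCoords(traj, k) * 10
        writeLines(sprintf(
            "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(nrow(a)), substr(a$name, 1, 4),
            substr(a$residue_name, 1, 3), a$residue_id %% 10000L,
            xyz[, 1], xyz[, 2], xyz[, 3], toupper(a$element)), con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}
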