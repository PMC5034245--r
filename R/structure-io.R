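#' @include AllClasses.R utils-geometry.R
NULL

#' HelixStructure: a parsed macromolecular structure
#'
#' Thin normalized container over the atom records of a PDB or mmCIF file:
#' one row per atom of model 1, after altloc resolution (highest occupancy
#' wins, ties resolve to altloc 'A').
#'
#' @slot structureId identifier derived from the file name (or header).
#' @slot atoms data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `o`, `b`.
#' @export
setClass("HelixStructure",
  representation(structureId = "character", atoms = "data.frame"))

setMethod("show", "HelixStructure", function(object) {
  cat(sprintf("HelixStructure '%s': %d atoms, chains %s\n",
              object@structureId, nrow(object@atoms),
              paste(unique(object@atoms$chain), collapse = ", ")))
  invisible(object)
})

# altloc policy: within each (chain, resno, insert, elety) keep the record
# with the highest occupancy; ties resolve alphabetically so 'A' wins.
.resolveAltloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$eleno), , drop = FALSE]
}

.readPDBAtoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  atomLn <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atomLn) == 0)
    stop("empty structure: no ATOM/HETATM records in '", path, "'")
  bad <- atomLn[nchar(lines[atomLn]) < 54]
  if (length(bad))
    stop("ill-formed/truncated ATOM record at line ", bad[1], " of '", path, "'")
  # first model only
  endm <- which(rec == "ENDMDL")
  if (length(endm)) atomLn <- atomLn[atomLn < endm[1]]
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  keep <- seq_len(min(nrow(a), length(atomLn)))
  a <- a[keep, , drop = FALSE]
  data.frame(
    eleno = a$eleno, elety = trimws(a$elety),
    alt = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
}

# Minimal mmCIF atom_site reader (no installed R package parses mmCIF).
# Handles the standard whitespace-separated loop_ table with single/double
# quoting; multi-line semicolon text blocks do not occur in atom_site rows.
.readCIFAtoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagIdx <- grep("^_atom_site\\.", lines)
  if (length(tagIdx) == 0)
    stop("ill-formed mmCIF: no _atom_site loop in '", path, "'")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagIdx]))
  dataStart <- max(tagIdx) + 1
  rows <- list()
  tokenize <- function(ln) {
    m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", ln)[[1]]
    tk <- regmatches(ln, list(m))[[1]]
    gsub("^['\"]|['\"]$", "", tk)
  }
  for (i in dataStart:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (grepl("^(#|loop_|_|data_)", ln)) break
    tk <- tokenize(ln)
    if (length(tk) != length(tags))
      stop("ill-formed mmCIF atom_site row at line ", i, " of '", path,
           "': expected ", length(tags), " fields, found ", length(tk))
    rows[[length(rows) + 1]] <- tk
  }
  if (length(rows) == 0) stop("empty structure: no atom_site rows in '", path, "'")
  tbl <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tbl) <- tags
  pick <- function(primary, fallback) {
    if (primary %in% tags) tbl[[primary]]
    else if (fallback %in% tags) tbl[[fallback]]
    else stop("mmCIF atom_site lacks both ", primary, " and ", fallback)
  }
  dot <- function(x, repl = "") ifelse(x %in% c(".", "?"), repl, x)
  atoms <- data.frame(
    eleno = as.integer(tbl[["id"]]),
    elety = dot(pick("auth_atom_id", "label_atom_id")),
    alt = dot(if ("label_alt_id" %in% tags) tbl$label_alt_id else "."),
    resid = dot(pick("auth_comp_id", "label_comp_id")),
    chain = dot(pick("auth_asym_id", "label_asym_id"), "A"),
    resno = as.integer(dot(pick("auth_seq_id", "label_seq_id"), NA)),
    insert = dot(if ("pdbx_PDB_ins_code" %in% tags) tbl$pdbx_PDB_ins_code else "."),
    x = as.numeric(tbl[["Cartn_x"]]), y = as.numeric(tbl[["Cartn_y"]]),
    z = as.numeric(tbl[["Cartn_z"]]),
    o = if ("occupancy" %in% tags) as.numeric(dot(tbl$occupancy, "1")) else 1,
    b = if ("B_iso_or_equiv" %in% tags)
          as.numeric(dot(tbl$B_iso_or_equiv, "0")) else 0,
    stringsAsFactors = FALSE)
  mask <- if ("group_PDB" %in% tags) tbl$group_PDB %in% c("ATOM", "HETATM")
          else rep(TRUE, nrow(tbl))
  atoms <- atoms[mask, , drop = FALSE]
  if ("pdbx_PDB_model_num" %in% tags) {
    mdl <- tbl$pdbx_PDB_model_num[mask]
    atoms <- atoms[mdl == mdl[1], , drop = FALSE]
  }
  atoms
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parses the atom records of a structure file into a
#' [HelixStructure-class]. Only the first model of multi-model files is
#' used; alternate locations are resolved to the highest-occupancy record
#' (ties to altloc 'A').
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` is mmCIF, anything else PDB).
#' @param structureId identifier to attach; defaults to the file base name
#'   without extension.
#' @return a [HelixStructure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          structureId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") .readPDBAtoms(path) else .readCIFAtoms(path)
  atoms <- .resolveAltloc(atoms)
  if (is.null(structureId))
    structureId <- sub("\\.[^.]*$", "", basename(path))
  new("HelixStructure", structureId = structureId, atoms = atoms)
}

#' Define a helical segment by chain and residue range
#'
#' @param name segment label (e.g. "TM5c").
#' @param chain chain identifier, or `"*"` as a wildcard expanded by the
#'   command drivers.
#' @param start,end first and last author residue numbers, inclusive on
#'   both ends.
#' @return a `segmentDefinition` list.
#' @export
segmentDefinition <- function(name, chain, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("segment '", name, "': need integer start <= end")
  structure(list(name = as.character(name), chain = as.character(chain),
                 start = start, end = end),
            class = "segmentDefinition")
}

#' Extract a backbone segment from a structure
#'
#' Selects the residues of `sdef`'s chain within `[start, end]` (author
#' numbering, inclusive; insertion codes honored in sequence order), keeps
#' the backbone atoms N, C-alpha, C, O, drops residues missing any of the
#' four with a warning, and returns a [HelixSegment-class]. Coordinates
#' pass through unmodified.
#'
#' @param structure a [HelixStructure-class].
#' @param sdef a [segmentDefinition()] (concrete chain, not a wildcard).
#' @return a [HelixSegment-class].
#' @export
extractSegment <- function(structure, sdef) {
  stopifnot(is(structure, "HelixStructure"),
            inherits(sdef, "segmentDefinition"))
  if (sdef$chain == "*")
    stop("wildcard chain must be expanded to concrete chains before extraction")
  a <- structure@atoms
  if (!sdef$chain %in% a$chain)
    stop("chain '", sdef$chain, "' not found in structure '",
         structure@structureId, "'")
  a <- a[a$chain == sdef$chain & !is.na(a$resno) &
           a$resno >= sdef$start & a$resno <= sdef$end &
           a$elety %in% .ATOM_TYPES, , drop = FALSE]
  if (nrow(a) == 0)
    stop("no residues found for segment '", sdef$name, "' (", sdef$chain,
         " ", sdef$start, "-", sdef$end, ") in '", structure@structureId, "'")
  key <- paste(a$resno, a$insert, sep = "\r")
  resKeys <- unique(key[order(a$resno, a$insert)])
  keep <- resKeys[vapply(resKeys, function(k)
    all(.ATOM_TYPES %in% a$elety[key == k]), TRUE)]
  dropped <- setdiff(resKeys, keep)
  if (length(dropped)) {
    warning("segment '", sdef$name, "' in '", structure@structureId,
            "': dropped ", length(dropped),
            " residue(s) with incomplete backbone (",
            paste(gsub("\r", "", dropped), collapse = ", "), ")")
  }
  if (length(keep) == 0)
    stop("all residues of segment '", sdef$name, "' have incomplete backbone")
  nres <- length(keep)
  coords <- array(NA_real_, c(nres, 4, 3),
                  dimnames = list(NULL, .ATOM_TYPES, c("x", "y", "z")))
  resno <- integer(nres); insert <- character(nres)
  for (j in seq_along(keep)) {
    rows <- a[key == keep[j], , drop = FALSE]
    resno[j] <- rows$resno[1]; insert[j] <- rows$insert[1]
    for (A in .ATOM_TYPES) {
      r <- rows[rows$elety == A, , drop = FALSE][1, ]
      coords[j, A, ] <- c(r$x, r$y, r$z)
    }
  }
  new("HelixSegment", structureId = structure@structureId,
      chainId = sdef$chain, label = sdef$name, resno = resno,
      insert = insert, coords = coords)
}

#' Backbone dihedral angles of a chain
#'
#' Standard phi (C(i-1), N(i), CA(i), C(i)) and psi (N(i), CA(i), C(i),
#' N(i+1)) dihedrals for every residue of a chain with a complete N, CA, C
#' backbone. Dihedrals are undefined (NA) at chain termini and across chain
#' breaks, detected as consecutive-residue CA-CA distances above 4.5
#' Angstrom.
#'
#' @param structure a [HelixStructure-class].
#' @param chain chain identifier.
#' @return data.frame with columns `resno`, `insert`, `phi`, `psi`
#'   (degrees in [-180, 180), NA where undefined).
#' @export
computeDihedrals <- function(structure, chain) {
  stopifnot(is(structure, "HelixStructure"))
  a <- structure@atoms
  a <- a[a$chain == chain & a$elety %in% c("N", "CA", "C"), , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' not found or has no backbone")
  key <- paste(a$resno, a$insert, sep = "\r")
  resKeys <- unique(key[order(a$resno, a$insert)])
  getAtom <- function(k, A) {
    r <- a[key == k & a$elety == A, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  n <- length(resKeys)
  if (n < 3) {
    rk <- strsplit(resKeys, "\r")
    return(data.frame(resno = as.integer(vapply(rk, `[`, "", 1)),
                      insert = vapply(rk, function(x) if (length(x) > 1) x[2] else "", ""),
                      phi = NA_real_, psi = NA_real_))
  }
  N <- lapply(resKeys, getAtom, "N")
  CA <- lapply(resKeys, getAtom, "CA")
  C <- lapply(resKeys, getAtom, "C")
  linked <- function(i, j) {
    !is.null(CA[[i]]) && !is.null(CA[[j]]) &&
      .norm3(CA[[j]] - CA[[i]]) <= 4.5
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok <- !is.null(N[[i]]) && !is.null(CA[[i]]) && !is.null(C[[i]])
    if (ok && i > 1 && !is.null(C[[i - 1]]) && linked(i - 1, i))
      phi[i] <- .dihedral4(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    if (ok && i < n && !is.null(N[[i + 1]]) && linked(i, i + 1))
      psi[i] <- .dihedral4(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
  }
  rk <- strsplit(resKeys, "\r")
  data.frame(resno = as.integer(vapply(rk, `[`, "", 1)),
             insert = vapply(rk, function(x) if (length(x) > 1) x[2] else "", ""),
             phi = phi, psi = psi)
}

.PARAM_TABLE_COLS <- c("structure_id", "chain", "segment", "group_id",
                       "diameter", "omega", "s",
                       "r_N", "r_CA", "r_C", "r_O",
                       "t_N", "t_C", "t_O",
                       "phi_N", "phi_CA", "phi_C", "phi_O",
                       "mean_phase", "rmsd", "converged")

#' Tabulate helix fits
#'
#' One row per fit with the full parameter set: diameter, angular turn per
#' residue, pitch, the four radii, three axial offsets, four phases, mean
#' phase, rmsd and convergence flag, plus identifying metadata and optional
#' group assignment. Rows are sorted by (group, structure, chain) to match
#' the survey-plot ordering; numbers are reported at 6 significant digits.
#'
#' @param fits list of [HelixFit-class] objects.
#' @param groups optional group configuration from [readGroupConfig()] used
#'   to assign `group_id` (unassigned structures get NA).
#' @return data.frame in the fixed column order `structure_id`, `chain`,
#'   `segment`, `group_id`, `diameter`, `omega`, `s`, `r_N`, `r_CA`, `r_C`,
#'   `r_O`, `t_N`, `t_C`, `t_O`, `phi_N`, `phi_CA`, `phi_C`, `phi_O`,
#'   `mean_phase`, `rmsd`, `converged`.
#' @export
parameterTable <- function(fits, groups = NULL) {
  if (length(fits) == 0) stop("no fits to tabulate")
  rows <- lapply(fits, function(f) {
    stopifnot(is(f, "HelixFit"))
    p <- f@params
    data.frame(
      structure_id = f@segment@structureId, chain = f@segment@chainId,
      segment = f@segment@label,
      group_id = .lookupGroup(groups, f@segment@structureId, f@segment@chainId),
      diameter = signif(2 * mean(p@radii), 6), omega = signif(p@omega, 6),
      s = signif(p@s, 6),
      r_N = signif(p@radii[["N"]], 6), r_CA = signif(p@radii[["CA"]], 6),
      r_C = signif(p@radii[["C"]], 6), r_O = signif(p@radii[["O"]], 6),
      t_N = signif(p@t[["N"]], 6), t_C = signif(p@t[["C"]], 6),
      t_O = signif(p@t[["O"]], 6),
      phi_N = signif(p@phi[["N"]], 6), phi_CA = signif(p@phi[["CA"]], 6),
      phi_C = signif(p@phi[["C"]], 6), phi_O = signif(p@phi[["O"]], 6),
      mean_phase = signif(.circMean(p@phi), 6), rmsd = signif(f@rmsd, 6),
      converged = f@converged, stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  tbl <- tbl[order(is.na(tbl$group_id), tbl$group_id, tbl$structure_id,
                   tbl$chain, tbl$segment), , drop = FALSE]
  rownames(tbl) <- NULL
  tbl[, .PARAM_TABLE_COLS]
}

#' Write a parameter table as TSV
#'
#' @param fits list of [HelixFit-class] objects (or a data.frame already
#'   produced by [parameterTable()]).
#' @param path output file path.
#' @param groups optional group configuration, see [parameterTable()].
#' @return the written data.frame, invisibly.
#' @export
writeParameterTable <- function(fits, path, groups = NULL) {
  tbl <- if (is.data.frame(fits)) fits else parameterTable(fits, groups)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: '", dir, "'")
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tbl)
}

.lookupGroup <- function(groups, structureId, chain) {
  if (is.null(groups)) return(NA_integer_)
  for (g in groups) {
    for (m in g$members) {
      if (identical(toupper(m$pdb), toupper(structureId)) &&
          (is.null(m$chain) || identical(m$chain, chain)))
        return(as.integer(g$id))
    }
  }
  NA_integer_
}

.readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: '", path, "'")
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

#' Read a segment-definition config (YAML or JSON)
#'
#' The file holds a top-level `segments` list; each entry needs `name`,
#' `chain` (may be the wildcard `"*"`), `start` and `end`.
#'
#' @param path config file path.
#' @return list of [segmentDefinition()] objects.
#' @export
readSegmentConfig <- function(path) {
  cfg <- .readConfigFile(path)
  if (is.null(cfg$segments) || length(cfg$segments) == 0)
    stop("segment config '", path, "' must contain a non-empty 'segments' list")
  lapply(cfg$segments, function(s) {
    for (fld in c("name", "chain", "start", "end"))
      if (is.null(s[[fld]]))
        stop("segment config '", path, "': entry missing field '", fld, "'")
    segmentDefinition(s$name, s$chain, s$start, s$end)
  })
}

#' Read a structure-grouping config (YAML or JSON)
#'
#' The file holds a top-level `groups` list; each entry needs `id` and
#' `members` (a list of `{pdb, chain}` pairs; `chain` may be omitted to
#' cover all chains of an entry), with an optional `description`. A
#' (pdb, chain) pair may belong to at most one group.
#'
#' @param path config file path.
#' @return list of group records.
#' @export
readGroupConfig <- function(path) {
  cfg <- .readConfigFile(path)
  if (is.null(cfg$groups)) stop("group config '", path, "' must contain 'groups'")
  groups <- lapply(cfg$groups, function(g) {
    if (is.null(g$id)) stop("group config '", path, "': group missing 'id'")
    members <- lapply(g$members, function(m) {
      if (is.null(m$pdb)) stop("group config '", path, "': member missing 'pdb'")
      list(pdb = as.character(m$pdb),
           chain = if (is.null(m$chain)) NULL else as.character(m$chain))
    })
    list(id = as.integer(g$id),
         description = if (is.null(g$description)) "" else g$description,
         members = members)
  })
  keys <- unlist(lapply(groups, function(g)
    vapply(g$members, function(m)
      paste(toupper(m$pdb), if (is.null(m$chain)) "*" else m$chain), "")))
  if (anyDuplicated(keys))
    stop("group config '", path, "': (pdb, chain) pair assigned to more than one group: ",
         keys[duplicated(keys)][1])
  groups
}
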