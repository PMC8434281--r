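#' @importFrom stats optim optimize rnorm runif setNames uniroot median sd
#' @importFrom utils read.delim write.table head
NULL

#' Construct a structure object from an atom table
#'
#' The package-wide coordinate model: a flat atom table plus entry-level
#' metadata.  Coordinates are Angstrom; residues are identified by author
#' numbering (with insertion codes), matching how sites are referred to in
#' crystallographic depositions.
#'
#' @param id entry identifier (e.g. a 4-character PDB id)
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{elesy}, \code{x},
#'   \code{y}, \code{z}, \code{o}, \code{het}
#' @param resolution resolution in Angstrom, or NA if not applicable
#' @param method experimental method string, or NA
#' @return object of class \code{zt_structure}
#' @export
zt_structure <- function(id, atoms, resolution = NA_real_, method = NA_character_) {
  needed <- c("chain", "resno", "insert", "resid", "elety", "elesy",
              "x", "y", "z", "o", "het")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("zt_structure: atom table lacks columns: ",
                         paste(miss, collapse = ", "))
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, resolution = resolution,
                 method = method), class = "zt_structure")
}

#' @export
print.zt_structure <- function(x, ...) {
  cat("<zt_structure>", x$id, "\n")
  cat("  atoms:", nrow(x$atoms),
      " chains:", paste(unique(x$atoms$chain), collapse = ","), "\n")
  if (!is.na(x$resolution)) cat("  resolution:", x$resolution, "A\n")
  invisible(x)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parses an atomic model into the uniform coordinate table used by all
#' downstream stages.  Alternate locations are resolved to a single
#' conformer (highest occupancy; ties broken by the alphabetically first
#' altloc tag), hydrogens are dropped, waters and heteroatoms (including
#' zinc ions) are retained, and only the first model of multi-model files
#' is kept.  Resolution is read from REMARK 2 (PDB) or
#' \code{_refine.ls_d_res_high} (mmCIF) when present.
#'
#' @param path path to the coordinate file
#' @param format one of \code{"auto"}, \code{"pdb"}, \code{"mmcif"}
#' @return a \code{zt_structure}
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("read_structure: parse error in '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- "A"
  at$o[is.na(at$o)] <- 1
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1))
  elesy <- ifelse(is.na(elesy) | elesy == "", guess, toupper(elesy))
  at$elesy <- elesy
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  at <- resolve_altlocs(at)
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety, elesy = at$elesy,
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      het = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  hdr <- scan_header(path, format)
  id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  zt_structure(id = id, atoms = atoms, resolution = hdr$resolution,
               method = hdr$method)
}

# Deterministic altloc resolution: per (chain, resno, insert, elety) keep the
# highest-occupancy record; occupancy ties keep the alphabetically first tag.
# File order of the surviving atoms is preserved.
resolve_altlocs <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  pos <- seq_len(nrow(at))
  ord <- order(key, -at$o, at$alt)
  keep <- sort(pos[ord][!duplicated(key[ord])])
  at[keep, , drop = FALSE]
}

scan_header <- function(path, format) {
  res <- NA_real_; method <- NA_character_
  lines <- readLines(path, n = 2000L, warn = FALSE)
  if (format == "pdb") {
    r <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(r)) {
      m <- regmatches(r[1], regexpr("[0-9]+\\.[0-9]+", r[1]))
      if (length(m)) res <- as.numeric(m)
    }
    e <- grep("^EXPDTA", lines, value = TRUE)
    if (length(e)) method <- trimws(sub("^EXPDTA\\s*", "", e[1]))
  } else {
    r <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(r)) {
      m <- regmatches(r[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", r[1]))
      if (length(m)) res <- as.numeric(trimws(m))
    }
    e <- grep("_exptl\\.method", lines, value = TRUE)
    if (length(e)) method <- gsub("['\"]", "",
                                  trimws(sub(".*_exptl\\.method", "", e[1])))
  }
  list(resolution = res, method = method)
}

#' Write a structure to a PDB-format file
#'
#' Coordinates are written to three decimals with the element column
#' populated; zinc ions and other heteroatoms become HETATM records.
#'
#' @param s a \code{zt_structure}
#' @param path output file path
#' @return the path, invisibly
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "zt_structure"))
  at <- s$atoms
  if (nrow(at) == 0) stop("write_structure: structure has no atoms")
  if (any(nchar(at$elety) > 4))
    stop("write_structure: atom name longer than 4 characters: ",
         at$elety[which(nchar(at$elety) > 4)[1]])
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   elety = at$elety, o = at$o, b = rep(0, nrow(at)),
                   elesy = at$elesy)
  invisible(path)
}

#' Filter structures by crystallographic resolution
#'
#' Keeps structures whose resolution is at or below \code{max_res}
#' (boundary inclusive, i.e. "2.4 A or better" retains 2.4 A entries).
#' Structures without resolution metadata (e.g. NMR models) are excluded.
#'
#' @param structures list of \code{zt_structure}
#' @param max_res maximum resolution in Angstrom (> 0)
#' @return filtered list
#' @export
resolution_filter <- function(structures, max_res = 2.4) {
  stopifnot(max_res > 0)
  keep <- vapply(structures, function(s)
    !is.na(s$resolution) && s$resolution <= max_res, logical(1))
  structures[keep]
}

#' Download a PDB entry into a cache directory
#'
#' Convenience fetcher for 4-character PDB ids; never invoked implicitly by
#' the package or its tests (all tests run on generated fixtures).
#'
#' @param id 4-character PDB identifier
#' @param cache_dir directory for downloaded files
#' @param format \code{"pdb"} or \code{"mmcif"}
#' @return path to the downloaded (or cached) file
#' @export
fetch_pdb <- function(id, cache_dir = file.path(tempdir(), "zincturn_pdb"),
                      format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  stopifnot(nchar(id) == 4)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "pdb") "pdb" else "cif"
  dest <- file.path(cache_dir, paste0(tolower(id), ".", ext))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.%s", toupper(id), ext)
    utils::download.file(url, dest, quiet = TRUE)
  }
  dest
}

# ---- atom access helpers ----------------------------------------------------

# Coordinates of one named atom, or NULL if absent.
atom_xyz <- function(s, chain, resno, elety, insert = "") {
  at <- s$atoms
  i <- which(at$chain == chain & at$resno == resno &
               at$insert == insert & at$elety == elety)
  if (!length(i)) return(NULL)
  as.numeric(at[i[1], c("x", "y", "z")])
}

# Residue name at a position, or NA if the residue is absent.
residue_name <- function(s, chain, resno, insert = "") {
  at <- s$atoms
  i <- which(at$chain == chain & at$resno == resno & at$insert == insert)
  if (!length(i)) return(NA_character_)
  at$resid[i[1]]
}

# All residues of a chain as a data.frame (resno, insert, resid), ordered.
chain_residues <- function(s, chain) {
  at <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  u <- !duplicated(paste(at$resno, at$insert))
  data.frame(resno = at$resno[u], insert = at$insert[u],
             resid = at$resid[u], stringsAsFactors = FALSE)
}
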