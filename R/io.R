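## Readers and writers for the package's plain-text dialects:
## PDB-subset coordinates (via bio3d), 3-column scattering curves,
## PRE tables and restraint tables (TSV), and site tables.

chainLetters <- c(LETTERS, letters)

#' Write a conformer as a PDB-subset file
#'
#' Beads are written as ATOM records (one residue per bead, chain id per
#' subunit) through bio3d. Subunit naming, the state tag and the methyl
#' and tag site tables are preserved in REMARK 99 lines so that
#' \code{\link{readConformerPDB}} round-trips the object to coordinate
#' format precision (3 decimals).
#'
#' @param x a \linkS4class{Conformer}.
#' @param file output path.
#' @return invisibly, the chain-to-subunit map used.
#' @export
writeConformerPDB <- function(x, file) {
  subs <- unique(x@subunit)
  if (length(subs) > length(chainLetters))
    stop("too many subunits for PDB chain ids")
  chainOf <- setNames(chainLetters[seq_along(subs)], subs)
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(x@coords)),
                   type = rep("ATOM", nrow(x@coords)),
                   resno = x@resid, resid = rep("BEA", nrow(x@coords)),
                   chain = unname(chainOf[x@subunit]),
                   elety = x@atomName)
  remarks <- c(
    sprintf("REMARK  99 STATE %s", x@stateTag),
    sprintf("REMARK  99 SUBUNIT %s %s", unname(chainOf[subs]), subs),
    if (length(x@mobileSubunits))
      sprintf("REMARK  99 MOBILE %s", paste(x@mobileSubunits, collapse = " ")),
    if (nrow(x@methylSites) > 0)
      sprintf("REMARK  99 METHYL %s %.3f %.3f %.3f",
              rownames(x@methylSites), x@methylSites[, 1],
              x@methylSites[, 2], x@methylSites[, 3]),
    unlist(lapply(names(x@tagSites), function(tg)
      sprintf("REMARK  99 TAG %s %.3f %.3f %.3f", tg,
              x@tagSites[[tg]][, 1], x@tagSites[[tg]][, 2],
              x@tagSites[[tg]][, 3]))))
  writeLines(c(remarks, readLines(tmp)), file)
  unlink(tmp)
  invisible(chainOf)
}

#' Read a conformer from a PDB-subset file
#'
#' ATOM/HETATM records are parsed with bio3d; chain ids become subunit ids
#' (renamed through REMARK 99 SUBUNIT lines when present), occupancy is
#' ignored and 1-based residue numbering is preserved. REMARK 99 lines
#' written by \code{\link{writeConformerPDB}} restore the state tag,
#' mobile subunits and site tables.
#'
#' @param file path to a PDB file.
#' @return A \linkS4class{Conformer}.
#' @export
readConformerPDB <- function(file) {
  lines <- readLines(file)
  rem <- lines[startsWith(lines, "REMARK  99")]
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                  error = function(e)
                    stop("malformed PDB record in ", file, ": ",
                         conditionMessage(e)))
  at <- pdb$atom
  coords <- cbind(at$x, at$y, at$z)
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  subunit <- chain
  stateTag <- "other"
  mobile <- character()
  methyl <- list()
  tags <- list()
  for (ln in rem) {
    f <- strsplit(trimws(sub("^REMARK  99 ", "", ln)), "\\s+")[[1]]
    if (f[1] == "STATE") stateTag <- f[2]
    else if (f[1] == "SUBUNIT") subunit[chain == f[2]] <- f[3]
    else if (f[1] == "MOBILE") mobile <- f[-1]
    else if (f[1] == "METHYL") methyl[[f[2]]] <- as.numeric(f[3:5])
    else if (f[1] == "TAG")
      tags[[f[2]]] <- rbind(tags[[f[2]]], as.numeric(f[3:5]))
  }
  methylM <- if (length(methyl))
    do.call(rbind, methyl) else matrix(numeric(0), 0, 3)
  conformer(coords, subunit, stateTag = stateTag, mobileSubunits = mobile,
            methylSites = methylM, tagSites = tags,
            atomName = at$elety, resid = at$resno)
}

#' Load a pool of conformers from PDB files
#'
#' @param path a directory of \code{.pdb} files or a character vector of
#'   file paths.
#' @param siteTable optional site table (see \code{\link{readSiteTable}})
#'   applied to every conformer.
#' @param provenance pool label.
#' @return A \linkS4class{ConformerPool} with members named after the
#'   files.
#' @export
loadStructures <- function(path, siteTable = NULL, provenance = "loaded") {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.pdb$", full.names = TRUE) else path
  if (length(files) == 0L) stop("no PDB files found in ", path)
  members <- lapply(files, readConformerPDB)
  if (!is.null(siteTable))
    members <- lapply(members, applySiteTable, siteTable = siteTable)
  names(members) <- sub("\\.pdb$", "", basename(files))
  conformerPool(members, provenance = provenance)
}

#' Read a site table
#'
#' TSV with columns \code{site_id}, \code{kind} (\code{methyl} or
#' \code{tag}), \code{chain} (subunit id), \code{residue}, \code{atom};
#' used to extract site positions from conformer coordinates.
#'
#' @param file path.
#' @return data.frame.
#' @export
readSiteTable <- function(file)
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

#' Resolve a site table against a conformer's coordinates
#'
#' @param x a \linkS4class{Conformer}.
#' @param siteTable data.frame as from \code{\link{readSiteTable}}.
#' @return the conformer with methyl/tag sites filled in.
#' @export
applySiteTable <- function(x, siteTable) {
  methyl <- list()
  tags <- x@tagSites
  for (i in seq_len(nrow(siteTable))) {
    st <- siteTable[i, ]
    hit <- which(x@subunit == st$chain & x@resid == st$residue &
                 x@atomName == st$atom)
    if (length(hit) == 0L)
      stop("site ", st$site_id, " not resolvable (", st$chain, "/",
           st$residue, "/", st$atom, ")")
    pos <- x@coords[hit[1], ]
    if (st$kind == "methyl") methyl[[st$site_id]] <- pos
    else tags[[st$site_id]] <- rbind(tags[[st$site_id]], pos)
  }
  if (length(methyl)) {
    m <- do.call(rbind, methyl)
    x@methylSites <- rbind(x@methylSites, m)
  }
  x@tagSites <- tags
  validObject(x)
  x
}

#' Write a scattering curve as a 3-column .dat file
#'
#' Whitespace-delimited columns s, I, sigma with '#' comment headers
#' carrying the scheme and any provenance (e.g. the seed).
#'
#' @param curve a \linkS4class{SASCurve}.
#' @param file output path.
#' @param header extra comment lines (without the leading '#').
#' @export
writeSASCurve <- function(curve, file, header = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# scheme=%s", curve@scheme),
               paste0("# ", header)), con)
  write.table(data.frame(curve@s, curve@I, curve@sigma), con,
              row.names = FALSE, col.names = FALSE)
}

#' Read a 3-column .dat scattering curve
#'
#' @param file path; lines starting with '#' are comments (a
#'   \code{scheme=} comment is honoured).
#' @param scheme scheme name override.
#' @param nmUnits set TRUE if s is in 1/nm; it is converted to
#'   1/Angstrom.
#' @return A \linkS4class{SASCurve}.
#' @export
readSASCurve <- function(file, scheme = NULL, nmUnits = FALSE) {
  lines <- readLines(file)
  com <- lines[startsWith(lines, "#")]
  if (is.null(scheme)) {
    m <- regmatches(com, regexpr("scheme=\\S+", com))
    scheme <- if (length(m)) sub("scheme=", "", m[1]) else "unknown"
  }
  dat <- read.table(text = lines[!startsWith(lines, "#")])
  if (ncol(dat) < 3L) stop("curve file must have 3 columns: s, I, sigma")
  s <- dat[[1]]
  if (nmUnits) s <- s / 10
  sasCurve(s, dat[[2]], dat[[3]], scheme = scheme)
}

#' Write / read a PRE measurement table (TSV)
#'
#' Columns: methyl_id, tag_id, ratio, ratio_err, r2_dia_h, r2_dia_h_err,
#' r2_dia_hc, r2_dia_hc_err.
#'
#' @param x PRE data.frame.
#' @param file path.
#' @export
writePreTable <- function(x, file)
  write.table(x, file, sep = "\t", row.names = FALSE, quote = FALSE)

#' @rdname writePreTable
#' @export
readPreTable <- function(file)
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

#' Write / read a restraint table (TSV)
#'
#' The dialect of \code{\link{deriveRestraints}} (tag atom spec, OR-group
#' site list, target distance, lower/upper slack, type, mode);
#' round-trips through the reader, including infinite upper slacks.
#'
#' @param x restraint data.frame.
#' @param file path.
#' @export
writeRestraints <- function(x, file)
  write.table(x, file, sep = "\t", row.names = FALSE, quote = FALSE)

#' @rdname writeRestraints
#' @export
readRestraints <- function(file) {
  out <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  out$upper_slack <- as.numeric(out$upper_slack)
  out
}
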