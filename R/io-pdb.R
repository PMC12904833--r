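# The chromatin community reuses the atomistic PDB format for bead models,
# each tool with its own conventions. The reader below accepts the common
# pseudo-atom dialect (one ATOM/HETATM record per bin, chain = chromosome,
# residue number = bin index); the writer emits our own dialect, which
# refuses to abuse the 4-column resSeq field for genomic coordinates and
# instead records true bin starts in a trailing REMARK table.

#' Read a reinterpreted-PDB chromatin structure
#'
#' Each `ATOM`/`HETATM` record becomes one bin, in file order. The chain
#' identifier becomes the chromosome (single-character chains are prefixed
#' with `"chr"` so integer-like labels do not collide with real names);
#' residue number `r` becomes the interval
#' `[(r - 1) * resolution, r * resolution)`. Records are parsed by the
#' PDB 3.3 fixed columns first — tolerating residue numbers that overflow
#' rightward into the insertion-code column, as 5-digit bead indices do —
#' and fall back to whitespace splitting for loosely formatted files.
#' `TER`/`REMARK`/`HEADER` and other non-atom records are ignored, as is
#' any REMARK sidecar (too dialect-specific to trust in foreign files):
#' the resolution must be given explicitly.
#'
#' @param path file path.
#' @param resolution bin width in base pairs.
#' @return a [BinTable].
#' @seealso [writePdbDialect()]
#' @export
readPdbDialect <- function(path, resolution) {
  stopifnot(is.numeric(resolution), resolution >= 1)
  lines <- readStructureLines(path)
  atom <- grep("^(ATOM|HETATM)[ 0-9]", lines)
  if (!length(atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  parseOne <- function(line, lineno) {
    # fixed columns: chain 22, resSeq 23-26 (+27 for overflowed digits),
    # x 31-38, y 39-46, z 47-54
    chain <- trimws(substr(line, 22L, 22L))
    resseq <- trimws(substr(line, 23L, 27L))
    resseq <- sub("[A-Za-z]$", "", resseq)  # strip insertion code
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31L, 38L),
                                         substr(line, 39L, 46L),
                                         substr(line, 47L, 54L))))
    r <- suppressWarnings(as.numeric(resseq))
    if (!is.na(r) && r == floor(r) && all(is.finite(xyz)) && nzchar(chain))
      return(list(chain = chain, resseq = r, xyz = xyz))
    # whitespace fallback: ATOM serial name resName chain resSeq x y z ...
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) >= 9L) {
      r <- suppressWarnings(as.numeric(tok[6L]))
      xyz <- suppressWarnings(as.numeric(tok[7:9]))
      if (!is.na(r) && all(is.finite(xyz)))
        return(list(chain = tok[5L], resseq = r, xyz = xyz))
    }
    stop(sprintf("line %d: cannot parse ATOM record (non-numeric residue number or coordinates)",
                 lineno), call. = FALSE)
  }

  parsed <- lapply(atom, function(i) parseOne(lines[i], i))
  chain <- vapply(parsed, `[[`, character(1), "chain")
  r <- vapply(parsed, `[[`, numeric(1), "resseq")
  xyz <- do.call(rbind, lapply(parsed, `[[`, "xyz"))
  chrom <- ifelse(nchar(chain) == 1L, paste0("chr", chain), chain)
  binTable(data.frame(chrom = chrom, start = (r - 1) * resolution,
                      end = r * resolution,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]))
}

PDB_CHAIN_ALPHABET <- c(LETTERS, 0:9)

#' Write a structure in the package's PDB chromatin dialect
#'
#' Emits one `ATOM` record per bin (pseudo-atom `CA`, residue name `BIN`),
#' serials sequential in row order, with chromosomes mapped to chain
#' identifiers `A`–`Z` then `0`–`9` in order of first appearance. Genomic
#' starts can span nine digits and so are never stored in the 4-column
#' residue-number field: `resSeq` holds the within-chromosome bin index
#' (1-based) and the true interval of every bin is written losslessly in a
#' trailing `REMARK 350 BINPOS` table (`serial chrom start end`).
#'
#' With `strict = TRUE` any condition that would silently lose information
#' — more than 36 chromosomes (chain alphabet exhausted) or more than 9999
#' bins on one chromosome (`resSeq` overflow) — is an error; with
#' `strict = FALSE` the labels wrap and a warning is emitted (the REMARK
#' table still holds the truth).
#'
#' @param x a [BinTable].
#' @param path output path.
#' @param strict error instead of wrapping on chain/resSeq exhaustion.
#' @return invisibly, `path`.
#' @seealso [readPdbDialect()]
#' @export
writePdbDialect <- function(x, path, strict = FALSE) {
  stopifnot(is(x, "BinTable"))
  cs <- unique(chroms(x))
  if (length(cs) > length(PDB_CHAIN_ALPHABET)) {
    if (strict)
      stop(sprintf("chain alphabet exhausted: chromosome %d ('%s') has no PDB chain id (36 available)",
                   length(PDB_CHAIN_ALPHABET) + 1L, cs[length(PDB_CHAIN_ALPHABET) + 1L]),
           call. = FALSE)
    warning("more than 36 chromosomes: chain identifiers wrap; ",
            "rely on the REMARK 350 BINPOS table for identity", call. = FALSE)
  }
  chainOf <- PDB_CHAIN_ALPHABET[((match(chroms(x), cs) - 1L) %%
                                   length(PDB_CHAIN_ALPHABET)) + 1L]
  idx <- stats::ave(seq_len(nbins(x)), chroms(x), FUN = seq_along)
  if (any(idx > 9999L)) {
    if (strict)
      stop("resSeq overflow: a chromosome has more than 9999 bins", call. = FALSE)
    warning("more than 9999 bins on a chromosome: resSeq wraps; ",
            "rely on the REMARK 350 BINPOS table for identity", call. = FALSE)
    idx <- ((idx - 1L) %% 9999L) + 1L
  }
  serial <- ((seq_len(nbins(x)) - 1L) %% 99999L) + 1L
  xyz <- coords(x)
  atoms <- sprintf("ATOM  %5d  CA  BIN %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                   serial, chainOf, idx, xyz[, 1L], xyz[, 2L], xyz[, 3L])
  remarks <- c("REMARK 350 BINPOS SERIAL CHROM START END",
               sprintf("REMARK 350 BINPOS %d %s %s %s",
                       serial, chroms(x), formatBp(binStarts(x)),
                       formatBp(binEnds(x))))
  writeLines(c(atoms, "TER", remarks, "END"), path)
  invisible(path)
}

#' Recover the genomic table from this package's own PDB dialect
#'
#' Parses the `REMARK 350 BINPOS` sidecar written by [writePdbDialect()],
#' returning the exact per-bin chromosome and interval (something the
#' ATOM records alone cannot carry). Only meaningful on files this
#' package wrote.
#'
#' @param path file path.
#' @return data.frame with columns `serial`, `chrom`, `start`, `end`.
#' @export
readPdbBinposSidecar <- function(path) {
  lines <- readStructureLines(path)
  tab <- grep("^REMARK 350 BINPOS [0-9]", lines, value = TRUE)
  if (!length(tab)) stop("no REMARK 350 BINPOS table in ", path, call. = FALSE)
  tok <- do.call(rbind, strsplit(tab, "\\s+"))
  data.frame(serial = as.integer(tok[, 4L]), chrom = tok[, 5L],
             start = as.numeric(tok[, 6L]), end = as.numeric(tok[, 7L]),
             stringsAsFactors = FALSE)
}
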