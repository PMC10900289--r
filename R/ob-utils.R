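# Internal wrappers around Open Babel (via ChemmineOB) used by the chemistry
# layer. All wrappers are batch-first: Open Babel start-up dominates per-call
# cost, so vectors of SMILES are converted in one call, with per-molecule
# fallback only for inputs the batch converter drops (i.e. parse failures).

.ob_opts <- function(...) {
  opts <- c(...)
  if (length(opts) == 0L) {
    return(data.frame(names = character(), args = character()))
  }
  data.frame(names = names(opts), args = unname(opts), stringsAsFactors = FALSE)
}

# Convert a character vector of SMILES with Open Babel. `to` is an Open Babel
# output format ("CAN", "SMI", "INCHI"). Returns a character vector aligned
# with `smiles`; inputs Open Babel cannot parse come back as NA.
ob_convert <- function(smiles, to = "CAN", ph = NULL, neutralize = FALSE) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  opts <- character()
  if (isTRUE(neutralize)) opts <- c(opts, neutralize = "")
  if (!is.null(ph)) opts <- c(opts, p = format(ph))
  ids <- paste0("x", seq_len(n))
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  out <- rep(NA_character_, n)
  convert_block <- function(idx) {
    src <- paste(paste(smiles[idx], ids[idx]), collapse = "\n")
    raw <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", to, src, options = .ob_opts(opts))),
      error = function(e) ""
    )
    lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    res <- rep(NA_character_, length(idx))
    if (length(lines)) {
      if (to == "INCHI") {
        # InChI output has no title column; it is one line per molecule in
        # input order but stops at the first failure, so only accept a full
        # batch here and let the fallback handle partial ones.
        if (length(lines) == length(idx) && all(startsWith(lines, "InChI="))) {
          res <- trimws(lines)
        }
      } else {
        parts <- strsplit(lines, "\t", fixed = TRUE)
        val <- vapply(parts, `[`, "", 1L)
        ttl <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""))
        hit <- match(ids[idx], ttl)
        res <- trimws(val[hit])
      }
    }
    res
  }
  if (any(ok)) {
    idx <- which(ok)
    out[idx] <- convert_block(idx)
    # batch conversion stops at the first unparseable input; retry the
    # missing ones one at a time so one bad SMILES cannot mask the rest
    miss <- which(ok & is.na(out))
    for (i in miss) out[i] <- convert_block(i)
  }
  out[!nzchar(trimws(out)) & !is.na(out)] <- NA_character_
  out
}

# Parse SMILES into Open Babel molecule references for fingerprinting and
# SMARTS matching. Unparseable inputs are an error: callers operate on
# standardized SMILES, which are valid by construction.
ob_parse <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  src <- paste(paste(smiles, paste0("x", seq_along(smiles))), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  if (length(mols) != length(smiles)) {
    stop("failed to parse ", length(smiles) - length(mols), " SMILES with Open Babel")
  }
  mols
}

# Batch SDF -> canonical SMILES via one obabel process (titles preserved for
# alignment); falls back to in-process conversion without the executable.
ob_sdf_to_can <- function(sdf_text, n_expected) {
  parse_lines <- function(lines) {
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    val <- vapply(parts, `[`, "", 1L)
    ttl <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""))
    stats::setNames(trimws(val), ttl)
  }
  if (Sys.which("obabel") != "") {
    fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".can")
    on.exit(unlink(c(fin, fout)))
    writeLines(sdf_text, fin)
    status <- suppressWarnings(system2("obabel", c(fin, "-ocan", "-O", fout),
                                       stdout = FALSE, stderr = FALSE))
    if (status == 0L && file.exists(fout)) {
      out <- parse_lines(readLines(fout))
      if (length(out) == n_expected) return(out)
    }
  }
  parse_lines(strsplit(suppressWarnings(
    ChemmineOB::convertFormat("SDF", "CAN", sdf_text)), "\n", fixed = TRUE)[[1]])
}

# Binary fingerprint matrix for a SMILES vector, computed in one obabel
# process (fast, and avoids the native-memory growth of repeated in-process
# fingerprinting). FP2 (1024-bit path fingerprints) backs the substructure
# prescreen; ECFP4 (4096-bit circular) backs the structure feature space.
# Falls back to in-process fingerprinting when the executable is missing.
ob_fpt_matrix <- function(smiles, type = "FP2", nbits = 1024L) {
  n <- length(smiles)
  hexlen <- nbits / 4L
  via_cli <- function() {
    if (Sys.which("obabel") == "") return(NULL)
    fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".fpt")
    on.exit(unlink(c(fin, fout)))
    writeLines(smiles, fin)
    status <- suppressWarnings(system2("obabel",
                                       c(fin, "-ofpt", paste0("-xf", type), "-xh"),
                                       stdout = fout, stderr = FALSE))
    if (status != 0L || !file.exists(fout)) return(NULL)
    lines <- readLines(fout)
    is_hdr <- grepl("^>", lines)
    rec <- cumsum(is_hdr)
    # keep only hex dump lines: obabel interleaves notes such as
    # "Possible superstructure of first mol" with the fingerprints
    is_hex <- !is_hdr & grepl("^[0-9a-fA-F ]+$", lines) & nzchar(trimws(lines))
    body <- split(lines[is_hex], rec[is_hex])
    hex <- gsub("[^0-9a-fA-F]", "",
                vapply(body, paste, "", collapse = ""))
    hex <- hex[order(as.integer(names(body)))]
    if (length(hex) != n || any(nchar(hex) != hexlen)) return(NULL)
    nib <- strtoi(strsplit(paste(hex, collapse = ""), "")[[1]], base = 16L)
    bits <- matrix(c(bitwAnd(nib, 8L) > 0, bitwAnd(nib, 4L) > 0,
                     bitwAnd(nib, 2L) > 0, bitwAnd(nib, 1L) > 0),
                   nrow = length(nib))
    matrix(as.numeric(t(bits)), nrow = n, byrow = TRUE)
  }
  out <- via_cli()
  if (!is.null(out)) return(out)
  mols <- ob_parse(smiles)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 200))
  do.call(rbind, lapply(chunks, function(ix) {
    matrix(as.numeric(ChemmineOB::fingerprint_OB(mols[ix], type)),
           nrow = length(ix))
  }))
}

ob_fp2_matrix <- function(smiles) ob_fpt_matrix(smiles, "FP2", 1024L)

# TRUE where the SMILES contains at least one carbon atom. "Cl" is chlorine,
# not carbon; bracket atoms are inspected for a C/c element symbol.
contains_carbon <- function(smiles) {
  stripped <- gsub("\\[[0-9]*(se|as|[A-Z][a-z]?|[a-z])[^]]*\\]",
                   "<\\1>", smiles)
  grepl("<C>|<c>", stripped) |
    grepl("C(?!l)|c", gsub("<[^>]*>", "", stripped), perl = TRUE)
}

# Count heavy (non-hydrogen) atoms in a SMILES string by tokenizing atom
# symbols. Bracket atoms count as one heavy atom unless they are [H]/[2H]/...
count_heavy_atoms <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_integer_)
    n <- 0L
    i <- 1L
    chars <- strsplit(s, "")[[1]]
    len <- length(chars)
    while (i <= len) {
      ch <- chars[i]
      if (ch == "[") {
        j <- i
        while (j <= len && chars[j] != "]") j <- j + 1L
        tok <- paste(chars[i:j], collapse = "")
        if (!grepl("^\\[[0-9]*H[+-]?[0-9]*\\]$", tok)) n <- n + 1L
        i <- j + 1L
      } else if (ch %in% c("C", "N", "O", "P", "S", "F", "I", "B")) {
        # two-letter organic-subset symbols
        if (ch == "C" && i < len && chars[i + 1L] == "l") i <- i + 1L
        if (ch == "B" && i < len && chars[i + 1L] == "r") i <- i + 1L
        n <- n + 1L
        i <- i + 1L
      } else if (ch %in% c("c", "n", "o", "p", "s", "b")) {
        n <- n + 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}
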