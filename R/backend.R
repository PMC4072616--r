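#' Thermodynamic backends
#'
#' All free energies in the package flow through a small backend contract:
#' `fold_mfe()` (single-strand minimum-free-energy structure) and
#' `hybridize_mfe()` (intermolecular duplex MFE of a short sequence against
#' a long one).  Two adapters implement it:
#'
#' * `"vienna"` — the ViennaRNA command-line programs `RNAfold` and
#'   `RNAduplex` (full nearest-neighbor model, 37 degrees C, minimum
#'   hairpin loop of 3).  This is the default and the engine all reported
#'   energies come from.
#' * `"basic"` — a built-in simplified Nussinov-with-stacking scorer
#'   (G-C -3, A-U -2, G.U -1 kcal/mol, stacking bonus -1).  It preserves
#'   the sign structure of pair gain/loss and is intended for fast unit
#'   tests; its absolute energies are not calibrated.
#'
#' Both adapters use the open-chain floor: a sequence whose best structure
#' is not stabilizing gets the all-unpaired structure with dG = 0.
#'
#' @param backend `"vienna"` or `"basic"`.
#' @return `fold_backend()` returns the validated backend name with the
#'   engine version as attribute `"version"`.
#' @examples
#' fold_backend("basic")
#' @export
fold_backend <- function(backend = c("vienna", "basic")) {
  backend <- match.arg(backend)
  version <- if (backend == "vienna") {
    if (!nzchar(Sys.which("RNAfold"))) {
      stop("RNAfold not found on PATH; use backend = \"basic\" or install ViennaRNA",
        call. = FALSE
      )
    }
    v <- suppressWarnings(system2("RNAfold", "--version", stdout = TRUE, stderr = TRUE))
    trimws(v[1])
  } else {
    "mirsnpscan built-in Nussinov-with-stacking"
  }
  structure(backend, version = version)
}

check_rna <- function(sequences, what = "sequence") {
  if (length(sequences) == 0) return(character(0))
  if (any(!nzchar(sequences))) stop("empty ", what, call. = FALSE)
  bad <- grepl("[^ACGU]", sequences)
  if (any(bad)) {
    stop(sprintf(
      "non-RNA character in %s: '%s' (normalize with normalize_rna())",
      what, sequences[which(bad)[1]]
    ), call. = FALSE)
  }
  sequences
}

#' Minimum-free-energy folding
#'
#' Folds each sequence and returns its MFE structure in dot-bracket
#' notation together with its free energy in kcal/mol.  Deterministic for
#' a fixed sequence and backend.
#'
#' @param sequences character vector of RNA sequences (`ACGU`).
#' @inheritParams fold_backend
#' @return a tibble with columns `sequence`, `structure`, `dg`.
#' @examples
#' fold_mfe(c("AAAAAAAA", "GGGGGAAAACCCCC"), backend = "basic")
#' @export
fold_mfe <- function(sequences, backend = c("vienna", "basic")) {
  backend <- match.arg(backend)
  check_rna(sequences)
  if (length(sequences) == 0) {
    return(tibble::tibble(
      sequence = character(), structure = character(), dg = numeric()
    ))
  }
  uniq <- unique(sequences)
  res <- if (backend == "vienna") vienna_fold(uniq) else basic_fold(uniq)
  idx <- match(sequences, uniq)
  tibble::tibble(
    sequence = sequences,
    structure = res$structure[idx],
    dg = res$dg[idx]
  )
}

vienna_fold <- function(sequences) {
  fold_backend("vienna")
  out <- system2("RNAfold", c("--noPS", "--noconv"),
    input = sequences, stdout = TRUE, stderr = FALSE
  )
  if (length(out) != 2L * length(sequences)) {
    stop("unexpected RNAfold output (", length(out), " lines for ",
      length(sequences), " sequences)",
      call. = FALSE
    )
  }
  struct_lines <- out[seq(2, length(out), by = 2)]
  m <- stringr::str_match(struct_lines, "^([.()]+)\\s+\\(\\s*(-?\\d+\\.?\\d*)\\)$")
  if (anyNA(m[, 1])) {
    stop("could not parse RNAfold output line: ", struct_lines[which(is.na(m[, 1]))[1]],
      call. = FALSE
    )
  }
  apply_dg_floor(m[, 2], as.numeric(m[, 3]))
}

basic_fold <- function(sequences) {
  res <- lapply(sequences, nussinov_fold_cpp)
  apply_dg_floor(
    vapply(res, `[[`, character(1), "structure"),
    vapply(res, `[[`, numeric(1), "dg")
  )
}

apply_dg_floor <- function(structure, dg) {
  open <- dg >= 0
  structure[open] <- strrep(".", nchar(structure[open]))
  dg[open] <- 0
  list(structure = structure, dg = dg)
}

#' Size of the terminal hairpin loop of a structure
#'
#' Returns the number of unpaired bases enclosed by the innermost base pair
#' of the 3'-most hairpin loop of a dot-bracket structure; for a structure
#' with no pairs, the full sequence length.
#'
#' @param structure character vector of dot-bracket strings.
#' @return integer vector of loop sizes in nucleotides.
#' @examples
#' loop_size("((((....))))")
#' loop_size("..........")
#' @export
loop_size <- function(structure) {
  iv <- loop_interval(structure)
  vapply(iv, function(x) x[2] - x[1] + 1L, integer(1))
}

# [start, end] of the 3'-most hairpin loop, full range when unpaired
loop_interval <- function(structure) {
  lapply(structure, function(s) {
    m <- gregexpr("\\(\\.*\\)", s)[[1]]
    if (m[1] == -1) {
      return(c(1L, nchar(s)))
    }
    i <- length(m) # 3'-most hairpin loop
    start <- m[i] + 1L
    end <- m[i] + attr(m, "match.length")[i] - 2L
    c(as.integer(start), as.integer(end))
  })
}

#' Intermolecular hybridization energy
#'
#' Minimum free energy of hybridizing a short RNA (a mature miRNA arm)
#' against any site of a long RNA (a 3'UTR), with no intramolecular pairs
#' in either molecule (the RNAhybrid model).  Energies are floored at 0:
#' a pair of sequences that cannot form a stabilizing hybrid scores 0.
#'
#' @param short_seq,long_seq character vectors (recycled to common length)
#'   of the miRNA and UTR sequences; each UTR must be at least as long as
#'   its miRNA.
#' @inheritParams fold_backend
#' @return numeric vector of hybridization energies (kcal/mol, <= 0).
#' @examples
#' hybridize_mfe("UAGCUUAUCA", "AAUGAUAAGCUAAA", backend = "basic")
#' @export
hybridize_mfe <- function(short_seq, long_seq, backend = c("vienna", "basic")) {
  backend <- match.arg(backend)
  check_rna(short_seq, "mature sequence")
  check_rna(long_seq, "UTR sequence")
  n <- max(length(short_seq), length(long_seq))
  if (n == 0) return(numeric(0))
  short_seq <- rep_len(short_seq, n)
  long_seq <- rep_len(long_seq, n)
  if (any(nchar(long_seq) < nchar(short_seq))) {
    stop("UTR sequence shorter than the mature sequence", call. = FALSE)
  }
  e <- if (backend == "vienna") {
    key <- paste(short_seq, long_seq)
    uniq <- !duplicated(key)
    eu <- vienna_duplex(short_seq[uniq], long_seq[uniq])
    eu[match(key, key[uniq])]
  } else {
    mapply(duplex_mfe_cpp, short_seq, long_seq, USE.NAMES = FALSE)
  }
  pmin(e, 0)
}

vienna_duplex <- function(short_seq, long_seq) {
  fold_backend("vienna")
  input <- as.vector(rbind(short_seq, long_seq))
  out <- system2("RNAduplex", "--noconv", input = input, stdout = TRUE, stderr = FALSE)
  out <- out[nzchar(trimws(out))]
  if (length(out) != length(short_seq)) {
    stop("unexpected RNAduplex output (", length(out), " lines for ",
      length(short_seq), " pairs)",
      call. = FALSE
    )
  }
  e <- stringr::str_match(out, "\\(\\s*(-?\\d+\\.?\\d*)\\)\\s*$")[, 2]
  if (anyNA(e)) {
    stop("could not parse RNAduplex output line: ", out[which(is.na(e))[1]],
      call. = FALSE
    )
  }
  as.numeric(e)
}
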