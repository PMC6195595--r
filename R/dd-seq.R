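#' Docking-domain sequence records
#'
#' A `dd_seq` bundles a docking-domain sequence with its role in the
#' megasynthase (`"NDD"` for an N-terminal acceptor domain, `"CDD"` for a
#' C-terminal donor domain) and the residue-numbering offset that maps sequence
#' index 1 to the residue number in the parent protein. For example the
#' Kj12B C-terminal docking domain peptide spans residues 1545-1568 of Kj12B,
#' so its offset is 1545.
#'
#' @param sequence one-letter amino-acid string (canonical residues only)
#' @param id identifier, e.g. `"Kj12B-CDD"`
#' @param role `"NDD"` or `"CDD"`
#' @param offset integer; parent-protein residue number of sequence index 1
#' @param notes free-text annotation (e.g. "non-native N-terminal tyrosine")
#' @return an object of class `dd_seq`
#' @examples
#' kj12b <- dd_seq("LLKEKRKHFQAEQNSSQEYLRGEI", "Kj12B-CDD", "CDD", offset = 1545)
#' beta3_register(kj12b)
#' @export
dd_seq <- function(sequence, id, role = c("CDD", "NDD"), offset = 1L,
                   notes = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  check_canonical(sequence, id)
  if (role == "CDD" && nchar(sequence) < 5) {
    abort("a CDD sequence must be at least 5 residues long",
          class = "nrpsdock_length_error")
  }
  structure(
    list(id = id, role = role, sequence = sequence,
         offset = as.integer(offset), notes = notes),
    class = "dd_seq"
  )
}

#' @export
print.dd_seq <- function(x, ...) {
  cat(sprintf("<dd_seq> %s [%s] residues %d-%d\n  %s\n", x$id, x$role,
              x$offset, x$offset + nchar(x$sequence) - 1L, x$sequence))
  if (!is.null(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' @export
length.dd_seq <- function(x) nchar(x$sequence)

#' Residue numbers covered by a docking-domain sequence
#' @param x a [dd_seq()]
#' @return integer vector, one entry per residue
#' @export
residue_numbers <- function(x) {
  stopifnot(inherits(x, "dd_seq"))
  seq(x$offset, x$offset + nchar(x$sequence) - 1L)
}

#' Extract the C-terminal beta3 register of a CDD
#'
#' Complex formation between these docking domains involves only the last five
#' C-terminal residues of the CDD, which form an extra antiparallel strand
#' (beta3) against strand beta2 of the NDD. This returns those residues with
#' relative positions -k..-1 (-1 = C-terminus) and their parent residue
#' numbers.
#'
#' @param cdd a [dd_seq()] with role `"CDD"`
#' @param k number of C-terminal residues (default 5)
#' @return a tibble of class `beta3_register` with columns `position`
#'   (-k..-1), `aa`, `residue_number`; the source id is kept as an attribute
#' @export
beta3_register <- function(cdd, k = 5L) {
  stopifnot(inherits(cdd, "dd_seq"))
  if (cdd$role != "CDD") {
    abort("beta3 registers are defined for CDD sequences only",
          class = "nrpsdock_role_error")
  }
  n <- nchar(cdd$sequence)
  if (n < k) {
    abort(sprintf("sequence %s has %d residues, fewer than k = %d",
                  cdd$id, n, k),
          class = "nrpsdock_length_error")
  }
  letters <- strsplit(cdd$sequence, "")[[1]]
  idx <- seq(n - k + 1L, n)
  out <- tibble(
    position = seq(-k, -1L),
    aa = letters[idx],
    residue_number = residue_numbers(cdd)[idx]
  )
  class(out) <- c("beta3_register", class(out))
  attr(out, "source_id") <- cdd$id
  out
}

#' Truncate a CDD to its n C-terminal residues
#'
#' Mirrors the short synthetic peptides used in binding studies (e.g. the
#' eight C-terminal residues of Kj12B-CDD, residues 1561-1568). The numbering
#' offset is advanced so parent residue numbers are preserved.
#'
#' @param cdd a [dd_seq()] with role `"CDD"`
#' @param n number of C-terminal residues to keep
#' @return a new [dd_seq()]
#' @export
truncate_cdd <- function(cdd, n) {
  stopifnot(inherits(cdd, "dd_seq"))
  len <- nchar(cdd$sequence)
  if (n > len) {
    abort(sprintf("cannot keep %d residues of a %d-residue sequence", n, len),
          class = "nrpsdock_length_error")
  }
  dd_seq(substr(cdd$sequence, len - n + 1L, len),
         id = paste0(cdd$id, "_", n, "C"),
         role = cdd$role,
         offset = cdd$offset + len - n,
         notes = cdd$notes)
}

#' Parse mutation strings like "R1565E"
#'
#' @param x character vector, each element `"<ref><number><alt>"`
#' @return a tibble with columns `residue_number`, `ref_aa`, `alt_aa`
#' @export
parse_mutations <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    abort(sprintf("cannot parse mutation spec(s): %s",
                  paste(x[bad], collapse = ", ")),
          class = "nrpsdock_parse_error")
  }
  out <- tibble(
    residue_number = as.integer(vapply(m, `[[`, "", 3L)),
    ref_aa = vapply(m, `[[`, "", 2L),
    alt_aa = vapply(m, `[[`, "", 4L)
  )
  same <- out$ref_aa == out$alt_aa
  if (any(same)) {
    abort(sprintf("mutation %s does not change the residue", x[same][1]),
          class = "nrpsdock_value_error")
  }
  out
}

#' Apply point mutations to a docking-domain sequence
#'
#' Mutations are specified in parent-protein numbering (resolved through the
#' sequence's numbering offset). In strict mode the current letter must match
#' the stated reference residue; in lenient mode mismatches are reported as
#' warnings and the substitution proceeds. Lenient mode exists because
#' published residue numbering for these peptides is not always internally
#' consistent.
#'
#' @param seq a [dd_seq()]
#' @param mutations a character vector like `c("R1565E")` or a tibble from
#'   [parse_mutations()]
#' @param strict logical (default `TRUE`)
#' @return a mutated [dd_seq()]
#' @export
apply_mutations <- function(seq, mutations, strict = TRUE) {
  stopifnot(inherits(seq, "dd_seq"))
  if (is.character(mutations)) mutations <- parse_mutations(mutations)
  if (nrow(mutations) == 0) return(seq)
  letters <- strsplit(seq$sequence, "")[[1]]
  nums <- residue_numbers(seq)
  idx <- match(mutations$residue_number, nums)
  if (anyNA(idx)) {
    missing <- mutations$residue_number[is.na(idx)]
    abort(sprintf("residue number(s) %s outside %s (%d-%d)",
                  paste(missing, collapse = ", "), seq$id,
                  min(nums), max(nums)),
          class = "nrpsdock_range_error")
  }
  mismatch <- letters[idx] != mutations$ref_aa
  if (any(mismatch)) {
    msg <- sprintf("position %d is %s, not %s",
                   mutations$residue_number[mismatch],
                   letters[idx][mismatch], mutations$ref_aa[mismatch])
    if (strict) {
      abort(paste0("reference mismatch: ", paste(msg, collapse = "; ")),
            class = "nrpsdock_reference_mismatch")
    }
    warn(paste0("reference mismatch (lenient mode): ",
                paste(msg, collapse = "; ")))
  }
  letters[idx] <- mutations$alt_aa
  label <- paste0(mutations$ref_aa, mutations$residue_number,
                  mutations$alt_aa, collapse = ",")
  dd_seq(paste(letters, collapse = ""),
         id = paste0(seq$id, "_", label),
         role = seq$role, offset = seq$offset, notes = seq$notes)
}

#' Monoisotopic neutral mass of a peptide
#'
#' Standard monoisotopic residue masses plus one water for the free termini.
#' @param peptide one-letter amino-acid string
#' @return neutral monoisotopic mass in Da
#' @export
monoisotopic_mass <- function(peptide) {
  letters <- check_canonical(peptide, "peptide")
  sum(AA_MONOISOTOPIC[letters]) + MASS_WATER
}

#' Monoisotopic m/z of a protonated peptide
#'
#' `(M + z * m_proton) / z` for the `[M + zH]^z+` ion, e.g.
#' `monoisotopic_mz("QEYARGEI", 2)` gives 483.2380.
#' @param peptide one-letter amino-acid string (free N- and C-termini,
#'   no modifications)
#' @param charge positive integer charge state
#' @return m/z value
#' @export
monoisotopic_mz <- function(peptide, charge = 1L) {
  if (!is.numeric(charge) || length(charge) != 1 || charge < 1 ||
      charge != round(charge)) {
    abort("charge must be a positive integer", class = "nrpsdock_value_error")
  }
  (monoisotopic_mass(peptide) + charge * MASS_PROTON) / charge
}

#' Percent identity between two sequences after global alignment
#'
#' Needleman-Wunsch global alignment (via Biostrings) with match +1,
#' mismatch 0, gap -1 by default; identity is the fraction of identical
#' aligned columns over the alignment length, as a percentage.
#'
#' @param a,b amino-acid strings or [dd_seq()] objects
#' @param match,mismatch,gap alignment scores
#' @return percentage in \[0, 100\]
#' @export
percent_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (inherits(a, "dd_seq")) a <- a$sequence
  if (inherits(b, "dd_seq")) b <- b$sequence
  if (!nzchar(a) || !nzchar(b)) {
    abort("sequences must be non-empty", class = "nrpsdock_value_error")
  }
  check_canonical(a, "a"); check_canonical(b, "b")
  mat <- matrix(mismatch, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pat == sub & pat != "-") / length(pat)
}

#' Read/write docking-domain FASTA
#'
#' The description line carries the role and numbering offset as key=value
#' tokens, e.g. `>Kj12B-CDD role=CDD offset=1545 note`.
#' @param path file path
#' @return `read_dd_fasta()`: a named list of [dd_seq()]
#' @export
read_dd_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nrpsdock_io_error")
  }
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    tokens <- strsplit(header, "\\s+")[[1]]
    id <- tokens[1]
    kv <- grep("=", tokens[-1], value = TRUE)
    keys <- sub("=.*", "", kv)
    vals <- sub(".*=", "", kv)
    fields <- setNames(as.list(vals), keys)
    note_tokens <- setdiff(tokens[-1], kv)
    dd_seq(as.character(set[[i]]), id = id,
           role = fields$role %||% "CDD",
           offset = as.integer(fields$offset %||% 1L),
           notes = if (length(note_tokens)) paste(note_tokens, collapse = " "))
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' @rdname read_dd_fasta
#' @param seqs a list of [dd_seq()]
#' @export
write_dd_fasta <- function(seqs, path) {
  if (inherits(seqs, "dd_seq")) seqs <- list(seqs)
  headers <- vapply(seqs, function(s) {
    paste0(s$id, " role=", s$role, " offset=", s$offset,
           if (!is.null(s$notes)) paste0(" ", gsub("\\s+", "_", s$notes)))
  }, "")
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "sequence"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
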