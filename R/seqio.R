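#' Read a FASTA file into sequence records
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file. The first
#' whitespace-delimited token of each header is the record id; the remainder
#' is kept as the description. Residues are uppercased and validated against
#' the declared alphabet.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"auto"` (default), `"protein"` or `"nucleotide"`. With
#'   `"auto"`, a record whose residues are all in `ACGTN` is called
#'   nucleotide, otherwise protein.
#' @return A data.frame with columns `id`, `description`, `residues`,
#'   `moltype`; zero rows for an empty file.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "MK", "VD"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, moltype = c("auto", "protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(data.frame(id = character(), description = character(),
                      residues = character(), moltype = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(gsub("\\s", "", as.character(set)))
  if (any(ids == "")) {
    stop("malformed FASTA header (empty id) at record ",
         which(ids == "")[1], call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record id in FASTA: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  empty <- which(nchar(residues) == 0)
  if (length(empty) > 0) {
    stop("empty sequence for record '", ids[empty[1]], "'", call. = FALSE)
  }
  mt <- vapply(residues, function(s) {
    if (moltype != "auto") return(moltype)
    chars <- unique(strsplit(s, "")[[1]])
    if (all(chars %in% NT_ALPHABET)) "nucleotide" else "protein"
  }, character(1), USE.NAMES = FALSE)
  for (i in seq_along(residues)) {
    alpha <- if (mt[i] == "nucleotide") NT_ALPHABET else AA_ALPHABET_X
    chars <- strsplit(residues[i], "")[[1]]
    bad <- which(!(chars %in% alpha))
    if (length(bad) > 0) {
      stop(sprintf("record '%s': invalid %s character '%s' at position %d",
                   ids[i], mt[i], chars[bad[1]], bad[1]), call. = FALSE)
    }
  }
  data.frame(id = ids, description = desc, residues = residues, moltype = mt)
}

#' Write sequence records to a FASTA file
#'
#' @param records data.frame with columns `id`, `residues` and optionally
#'   `description` (as produced by [read_fasta()]).
#' @param path Output file path.
#' @param width Line-wrap width for residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Stop codons are rendered as `*`. The input length must be a multiple of
#' three.
#'
#' @param codons Nucleotide string (`ACGTN`).
#' @return Protein string, one letter per codon.
#' @examples
#' translate_cds("ATGGCTTGA")  # "MA*"
#' @export
translate_cds <- function(codons) {
  codons <- toupper(codons)
  if (nchar(codons) %% 3 != 0) {
    stop("sequence length (", nchar(codons), ") is not a multiple of 3",
         call. = FALSE)
  }
  if (nchar(codons) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(codons),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "solve"))
}

#' Find the longest open reading frame in a cDNA sequence
#'
#' Scans the three forward frames (cDNA clones are assumed to be
#' directionally sequenced; set `both_strands = TRUE` for a 6-frame search)
#' for ATG-to-stop open reading frames and returns the longest one whose
#' peptide has at least `min_aa` residues. Ties are broken by the smaller
#' start position. Coordinates are 1-based and inclusive of the stop codon.
#'
#' @param record One-row data.frame as from [read_fasta()], or a plain
#'   nucleotide string.
#' @param min_aa Minimum peptide length in residues (default 50).
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return A list with `frame` (0, 1 or 2), `start`, `end`, `strand`
#'   (`"+"`/`"-"`), and `peptide` (stop excluded), or `NULL` if no ORF of the
#'   requested length exists.
#' @examples
#' find_longest_orf("CCATGAAATAGCC", min_aa = 1)
#' @export
find_longest_orf <- function(record, min_aa = 50, both_strands = FALSE) {
  seq <- if (is.data.frame(record)) {
    if (!is.null(record$moltype) && any(record$moltype != "nucleotide")) {
      stop("find_longest_orf requires a nucleotide record", call. = FALSE)
    }
    record$residues[1]
  } else {
    as.character(record)
  }
  seq <- toupper(seq)
  best <- NULL
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (frame in 0:2) {
      usable <- nchar(s) - frame
      ncod <- usable %/% 3
      if (ncod < 2) next
      codons <- substring(s, frame + seq(1, by = 3, length.out = ncod),
                          frame + seq(3, by = 3, length.out = ncod))
      is_atg <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      prev_stop <- 0L
      for (j in which(is_stop)) {
        starts <- which(is_atg[(prev_stop + 1L):(j - 1L)])
        if (j - 1L >= prev_stop + 1L && length(starts) > 0) {
          a <- prev_stop + starts[1]          # earliest ATG => longest ORF
          len_aa <- j - a                      # codons before the stop
          if (len_aa >= min_aa &&
              (is.null(best) || len_aa > best$len_aa)) {
            nt_start <- frame + (a - 1L) * 3L + 1L
            nt_end <- frame + j * 3L
            pep <- translate_cds(substr(s, nt_start, nt_end - 3L))
            best <- list(frame = frame, start = nt_start, end = nt_end,
                         strand = strand, peptide = pep, len_aa = len_aa)
          }
        }
        prev_stop <- j
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$len_aa <- NULL
  best
}

#' Tabulate the longest ORF of each record
#'
#' @param records data.frame of nucleotide records from [read_fasta()].
#' @inheritParams find_longest_orf
#' @return data.frame with columns `id`, `frame`, `start`, `end`,
#'   `length_aa`; records without a qualifying ORF are omitted.
#' @export
orf_report <- function(records, min_aa = 50, both_strands = FALSE) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    orf <- find_longest_orf(records$residues[i], min_aa = min_aa,
                            both_strands = both_strands)
    if (is.null(orf)) return(NULL)
    data.frame(id = records$id[i], frame = orf$frame, start = orf$start,
               end = orf$end, length_aa = nchar(orf$peptide))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(), frame = integer(), start = integer(),
                      end = integer(), length_aa = integer())
  }
  out
}
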