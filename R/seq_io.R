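#' @keywords internal
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
.NT_ALPHABET <- c("A", "C", "G", "T", "U", "N")

#' Build a set of sequence records
#'
#' The pipeline's common currency is a plain data frame of named
#' sequences bound to a species and a source dataset. Residues are
#' stored upper-case; the declared alphabet (amino acid or nucleotide,
#' plus X/N ambiguity and `*` stop characters) is enforced on entry.
#'
#' @param id character vector of identifiers (unique within the set).
#' @param residues character vector of sequences.
#' @param species species name per record (recycled).
#' @param molecule_type `"protein"` or `"nucleotide"`.
#' @param source_dataset free-text dataset label (recycled).
#' @return data.frame with columns `id`, `species`, `residues`,
#'   `molecule_type`, `source_dataset`.
#' @export
sequence_records <- function(id, residues, species = "",
                             molecule_type = c("protein", "nucleotide"),
                             source_dataset = "") {
  molecule_type <- match.arg(molecule_type)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  if (anyDuplicated(id))
    stop("duplicate identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(id)) {
    if (any(!nzchar(residues)))
      stop("empty sequence for entry ",
           paste(id[!nzchar(residues)], collapse = ", "))
    alpha <- if (molecule_type == "protein") .AA_ALPHABET else .NT_ALPHABET
    bad <- vapply(strsplit(residues, ""),
                  function(ch) any(!ch %in% alpha), logical(1))
    if (any(bad)) {
      offend <- vapply(strsplit(residues[bad], ""), function(ch)
        paste(unique(setdiff(ch, alpha)), collapse = ""), character(1))
      stop("illegal characters in entry ", paste(id[bad], collapse = ", "),
           " (", paste(offend, collapse = ", "), ")")
    }
  }
  data.frame(id = id, species = rep_len(as.character(species), length(id)),
             residues = residues,
             molecule_type = rep_len(molecule_type, length(id)),
             source_dataset = rep_len(as.character(source_dataset), length(id)),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into sequence records
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]:
#' `>`-headers, arbitrary line wrap, blank lines ignored; `*` is
#' permitted in protein sequences (stops from translation). The first
#' whitespace token of each description line becomes the identifier.
#'
#' @param path FASTA file.
#' @param molecule_type `"protein"` or `"nucleotide"`.
#' @param species,source_dataset metadata attached to every record;
#'   `source_dataset` defaults to the file name.
#' @return sequence-record data.frame (see [sequence_records()]),
#'   entries in file order.
#' @export
read_fasta <- function(path, molecule_type = c("protein", "nucleotide"),
                       species = "", source_dataset = basename(path)) {
  molecule_type <- match.arg(molecule_type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0 ||
      !any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(sequence_records(character(), character(),
                            molecule_type = molecule_type))
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  lens <- Biostrings::width(ss)
  if (any(lens == 0))
    stop("malformed FASTA: entry \"", ids[which(lens == 0)[1]],
         "\" has an empty sequence")
  sequence_records(ids, as.character(ss), species = species,
                   molecule_type = molecule_type,
                   source_dataset = source_dataset)
}

#' Write sequence records to FASTA
#'
#' @param records sequence-record data.frame.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  ss <- Biostrings::BStringSet(setNames(records$residues, records$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Translate a nucleotide record in all six reading frames
#'
#' Frames +1..+3 and -1..-3 (on the reverse complement) under the
#' standard genetic code; stop codons are emitted as `*`, trailing
#' partial codons dropped, ambiguous codons (containing N) rendered as
#' `X`. The frame is recorded as an identifier suffix (`_frame+2` etc.).
#'
#' @param record a single-row nucleotide sequence record.
#' @return sequence-record data.frame of 6 protein records (frames with
#'   fewer than 3 usable bases are dropped).
#' @export
six_frame_translate <- function(record) {
  if (nrow(record) != 1L) stop("six_frame_translate takes a single record")
  if (record$molecule_type != "nucleotide")
    stop("six_frame_translate requires a nucleotide record")
  fwd <- Biostrings::DNAString(chartr("U", "T", record$residues))
  rev <- Biostrings::reverseComplement(fwd)
  out_id <- character(0); out_seq <- character(0)
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (frame > 0) fwd else rev
    off <- abs(frame) - 1L
    n_codon <- (length(s) - off) %/% 3L
    if (n_codon < 1L) next
    sub <- Biostrings::subseq(s, start = off + 1L, width = 3L * n_codon)
    aa <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "solve"))
    out_id <- c(out_id, sprintf("%s_frame%+d", record$id, frame))
    out_seq <- c(out_seq, aa)
  }
  sequence_records(out_id, out_seq, species = record$species,
                   molecule_type = "protein",
                   source_dataset = record$source_dataset)
}

#' Read a species manifest
#'
#' Canonical manifest layout: a 4-column TSV with header
#' `species`, `order`, `subphylum`, `dataset`. A `group_label` column is
#' derived for taxon summaries: the order for Hexapoda, otherwise the
#' subphylum (matching how arthropod presence maps are usually drawn,
#' with non-hexapod subphyla collapsed).
#'
#' @param path TSV file.
#' @return data.frame with columns `species`, `order`, `subphylum`,
#'   `dataset`, `group_label`.
#' @export
read_species_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "order", "subphylum")
  if (!all(need %in% names(m)))
    stop("manifest must have columns species, order, subphylum")
  if (is.null(m$dataset)) m$dataset <- ""
  if (anyDuplicated(m$species))
    stop("duplicate species in manifest: ",
         paste(unique(m$species[duplicated(m$species)]), collapse = ", "))
  if (any(!nzchar(m$order)) || any(!nzchar(m$subphylum)))
    stop("order and subphylum must be non-empty for every species")
  m$group_label <- ifelse(m$subphylum == "Hexapoda", m$order, m$subphylum)
  m[c("species", "order", "subphylum", "dataset", "group_label")]
}

#' Load the packaged reference peptide table
#'
#' The packaged census of oxytocin/vasopressin/inotocin-family mature
#' peptides: 3 vertebrate reference peptides (frequency 0) and 21
#' arthropod peptides with their observed precursor frequencies.
#' `amidated` marks peptides with a canonical C-terminal amidation;
#' `insect` marks peptides found in the class Insecta; `artefact` marks
#' the one peptide attributed to dataset contamination.
#'
#' @return data.frame with columns `sequence`, `amidated`, `frequency`,
#'   `name`, `group`, `insect`, `artefact`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_peptides.tsv",
                      package = "inotoscan", mustWork = TRUE)
  f <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  f$name[is.na(f$name)] <- ""
  f
}

#' Load the packaged order-level arthropod taxonomy tree
#'
#' A rooted Newick tree whose tips are the three non-hexapod subphyla
#' (Chelicerata, Myriapoda, Crustacea) and the hexapod orders, suitable
#' as input to [dollo_losses()].
#'
#' @return an [ape::read.tree()] `phylo` object.
#' @export
load_order_tree <- function() {
  ape::read.tree(system.file("extdata", "arthropod_orders.nwk",
                             package = "inotoscan", mustWork = TRUE))
}

#' Expand the fixture peptide table into one entry per precursor
#'
#' @param fixture as returned by [load_table1_fixture()].
#' @param insect_only keep only peptides of the class Insecta.
#' @param drop_artefact drop peptides flagged as contamination artefacts.
#' @param length_only keep only peptides of this length (NULL = all).
#' @return character vector of mature peptides, each repeated by its
#'   precursor frequency (vertebrate reference rows, frequency 0, drop out).
#' @export
expand_fixture_peptides <- function(fixture = load_table1_fixture(),
                                    insect_only = FALSE,
                                    drop_artefact = FALSE,
                                    length_only = NULL) {
  keep <- fixture$frequency > 0
  if (insect_only) keep <- keep & fixture$insect
  if (drop_artefact) keep <- keep & !fixture$artefact
  if (!is.null(length_only)) keep <- keep & nchar(fixture$sequence) == length_only
  rep(fixture$sequence[keep], fixture$frequency[keep])
}
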