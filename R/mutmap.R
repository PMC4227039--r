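# Mutation table ingest, filtering, reconciliation and per-residue tallies.
#
# The mutation table contract is a TSV with a header row and columns
# gene, sample_id, position, wt_aa, mut_aa, mutation_type, somatic_status,
# screen_type (UTF-8, 1-based protein positions). This replaces any
# database-specific extraction step with a documented flat-file interface.

MUTATION_COLUMNS <- c("gene", "sample_id", "position", "wt_aa", "mut_aa",
                      "mutation_type", "somatic_status", "screen_type")

ACCEPTED_STATUS <- c("confirmed somatic variant",
                     "reported in another cancer sample as somatic")
ACCEPTED_SCREENS <- c("whole_gene", "whole_genome")

#' Read a per-sample mutation table (TSV)
#'
#' @param path path to a tab-separated file with columns `gene`, `sample_id`,
#'   `position`, `wt_aa`, `mut_aa`, `mutation_type`, `somatic_status`,
#'   `screen_type`.
#' @return data.frame of mutation records.
#' @export
readMutations <- function(path) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(MUTATION_COLUMNS, names(df))
  if (length(missing))
    stop("mutation table is missing column(s): ", paste(missing, collapse = ", "))
  df$position <- suppressWarnings(as.integer(df$position))
  df
}

#' Write a mutation table (TSV)
#'
#' @param records data.frame of mutation records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMutationsTSV <- function(records, path) {
  utils::write.table(records[, MUTATION_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateMutationRecords <- function(records) {
  bad <- which(is.na(records$position) | records$position < 1)
  badAA <- which(!(toupper(records$wt_aa) %in% c(AA_LETTERS, "X")) |
                 !(toupper(records$mut_aa) %in% c(AA_LETTERS, "X")))
  problems <- character(0)
  if (length(bad))
    problems <- c(problems, paste0("invalid position in row(s) ",
                                   paste(bad, collapse = ", ")))
  if (length(badAA))
    problems <- c(problems, paste0("unknown residue letter in row(s) ",
                                   paste(badAA, collapse = ", ")))
  if (length(problems))
    stop("malformed mutation record(s): ", paste(problems, collapse = "; "))
  invisible(TRUE)
}

#' Filter mutation records to the analyzable subset
#'
#' Keeps records that are (i) missense, (ii) recorded with an accepted
#' somatic status ("confirmed somatic variant" or "reported in another cancer
#' sample as somatic"; matched case-insensitively after whitespace trimming),
#' and (iii) from whole-gene or whole-genome screens (avoiding selection
#' bias toward known hotspots). Exact duplicates on
#' (gene, sample_id, position, wt_aa, mut_aa) are then removed, keeping the
#' first occurrence, so that one cell line reported by several studies is
#' counted once.
#'
#' @param records data.frame of mutation records (see [readMutations()]).
#' @return filtered data.frame.
#' @export
filterMutations <- function(records) {
  if (nrow(records) == 0) return(records)
  validateMutationRecords(records)
  norm <- function(x) tolower(trimws(x))
  keep <- norm(records$mutation_type) == "missense" &
    norm(records$somatic_status) %in% ACCEPTED_STATUS &
    norm(records$screen_type) %in% ACCEPTED_SCREENS
  out <- records[keep, , drop = FALSE]
  key <- paste(out$gene, out$sample_id, out$position,
               toupper(out$wt_aa), toupper(out$mut_aa), sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconcile canonical mutation positions with structure residues
#'
#' Databases number mutations in the canonical protein sequence while
#' coordinate files use author numbering, so the two must be reconciled
#' before mutations can be placed on the structure. Two modes are provided:
#' `"structure_numbering"` trusts the author residue numbers (canonical
#' position p maps to the residue whose author number equals p), while
#' `"alignment"` performs a global pairwise alignment (BLOSUM62, gap opening
#' 10, gap extension 0.5) between the canonical sequence and the sequence
#' derived from the structure, mapping positions through aligned non-gap
#' columns.
#'
#' @param canonicalSeq canonical amino-acid sequence (character string);
#'   required for alignment mode.
#' @param model a [StructureModel-class].
#' @param mode `"alignment"` (default) or `"structure_numbering"`.
#' @param identityFloor minimum fraction of aligned identical residues below
#'   which reconciliation fails rather than risk a silently wrong mapping
#'   (default 0.90).
#' @return a [ResidueMapping-class].
#' @export
reconcile <- function(canonicalSeq = NULL, model,
                      mode = c("alignment", "structure_numbering"),
                      identityFloor = 0.90) {
  mode <- match.arg(mode)
  n <- nResidues(model)
  if (mode == "structure_numbering") {
    resno <- model@resno
    ok <- !is.na(resno) & resno >= 1 & !duplicated(resno)
    canonicalPos <- resno[ok]
    structureIdx <- seq_len(n)[ok]
    o <- order(canonicalPos)
    return(new("ResidueMapping", canonicalPos = as.integer(canonicalPos[o]),
               structureIdx = as.integer(structureIdx[o]),
               mode = mode, identity = NA_real_))
  }
  if (is.null(canonicalSeq) || !nzchar(canonicalSeq))
    stop("alignment mode requires a non-empty canonical sequence")
  structSeq <- residueSequence(model)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(canonicalSeq), Biostrings::AAString(structSeq),
    type = "global", substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- pat != "-" & sub != "-"
  identity <- if (any(both)) mean(pat[both] == sub[both]) else 0
  if (identity < identityFloor)
    stop("reconciliation-failed error: alignment identity ",
         sprintf("%.3f", identity), " below floor ", identityFloor)
  canonPosAll <- cumsum(pat != "-")
  structPosAll <- cumsum(sub != "-")
  new("ResidueMapping",
      canonicalPos = as.integer(canonPosAll[both]),
      structureIdx = as.integer(structPosAll[both]),
      mode = mode, identity = identity)
}

setMethod("show", "ResidueMapping", function(object) {
  cat("ResidueMapping (", object@mode, "): ",
      sum(!is.na(object@structureIdx)), " mapped position(s)",
      if (!is.na(object@identity))
        sprintf(", identity %.3f", object@identity) else "",
      "\n", sep = "")
})

#' Map canonical positions to structure residue indices
#'
#' @param mapping a [ResidueMapping-class].
#' @param positions integer canonical positions.
#' @return integer structure indices (NA where unmapped).
#' @export
mapPositions <- function(mapping, positions) {
  mapping@structureIdx[match(positions, mapping@canonicalPos)]
}

#' Aggregate filtered mutations into a per-residue tally
#'
#' Counts every mapped mutation occurrence at the sample level, so two
#' samples mutating the same residue contribute two occurrences. Occurrences
#' at canonical positions without structure coordinates (e.g. disordered
#' loops) are dropped and their number recorded.
#'
#' @param records filtered mutation records (see [filterMutations()]).
#' @param mapping a [ResidueMapping-class].
#' @param model a [StructureModel-class] (defines N for the structure-indexed
#'   counts).
#' @param canonicalSeq optional canonical sequence; when given, wild-type
#'   letters are checked against it and mismatches raise a warning (isoform
#'   drift between databases makes a hard error too brittle).
#' @return a [MutationTally-class].
#' @export
tallyMutations <- function(records, mapping, model, canonicalSeq = NULL) {
  n <- nResidues(model)
  structureCounts <- integer(n)
  if (nrow(records) == 0) {
    return(new("MutationTally", counts = setNames(integer(0), character(0)),
               structureCounts = structureCounts, total = 0L, nUnmapped = 0L))
  }
  if (!is.null(canonicalSeq)) {
    canon <- strsplit(canonicalSeq, "")[[1]]
    inside <- records$position <= length(canon)
    mism <- sum(toupper(records$wt_aa[inside]) !=
                  canon[records$position[inside]])
    if (mism > 0)
      warning(mism, " record(s) have wild-type letters disagreeing with the ",
              "canonical sequence")
  }
  sIdx <- mapPositions(mapping, records$position)
  mapped <- !is.na(sIdx)
  nUnmapped <- sum(!mapped)
  if (nUnmapped > 0)
    message(nUnmapped, " mutation occurrence(s) without structure ",
            "coordinates were dropped")
  tab <- table(records$position[mapped])
  counts <- setNames(as.integer(tab), names(tab))
  sTab <- table(sIdx[mapped])
  structureCounts[as.integer(names(sTab))] <- as.integer(sTab)
  new("MutationTally", counts = counts, structureCounts = structureCounts,
      total = sum(counts), nUnmapped = as.integer(nUnmapped))
}

#' @rdname accessors
#' @export
setMethod("mutationCounts", "MutationTally", function(x, ...) x@counts)

#' @rdname accessors
#' @export
setMethod("totalMutations", "MutationTally", function(x, ...) x@total)

#' @describeIn isBlank fewer than two mapped occurrences means no clustering
#'   is possible.
#' @export
setMethod("isBlank", "MutationTally", function(x) x@total < 2L)

setMethod("show", "MutationTally", function(object) {
  cat("MutationTally:", object@total, "mapped occurrence(s) at",
      length(object@counts), "position(s);", object@nUnmapped, "dropped\n")
})

#' Write a canonical-to-structure mapping report (TSV)
#'
#' @param mapping a [ResidueMapping-class].
#' @param model a [StructureModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMappingReport <- function(mapping, model, path) {
  df <- data.frame(
    canonical_position = mapping@canonicalPos,
    structure_position = ifelse(is.na(mapping@structureIdx), NA,
                                model@structurePos[mapping@structureIdx]),
    status = ifelse(is.na(mapping@structureIdx), "unmapped", "mapped"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the first sequence from a FASTA file
#'
#' @param path FASTA path.
#' @return character(1) amino-acid sequence.
#' @export
readFastaSequence <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  as.character(seqs[[1]])
}

#' Write a single-sequence FASTA file
#'
#' @param seq amino-acid sequence (character string).
#' @param name sequence header.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastaSequence <- function(seq, name, path) {
  x <- Biostrings::AAStringSet(seq)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
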