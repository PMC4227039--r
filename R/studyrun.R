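# Multi-structure study with rough-FDR adjustment.

#' Rough false-discovery-rate threshold across k structures
#'
#' When many positively correlated or independent tests are performed (many
#' structures of the same proteins), the rough FDR cutoff
#' alpha * (k + 1) / (2k) approximates the standard FDR control level. It
#' decreases in k from alpha (k = 1) toward alpha / 2 (k -> infinity).
#'
#' @param alpha nominal level, 0 < alpha < 1.
#' @param k number of analyzed structures (>= 1).
#' @return numeric threshold.
#' @examples
#' rfdrThreshold(0.05, 1110)  # ~0.025023
#' @export
rfdrThreshold <- function(alpha, k) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (k < 1) stop("k must be >= 1")
  alpha * (k + 1) / (2 * k)
}

#' Deterministic sub-seed from a master seed and a label
#'
#' Stable string hash folded with the master seed, kept below 2^31 so it is a
#' valid R seed. Used to give every structure in a study an independent,
#' manifest-order-free simulation stream.
#'
#' @param seed master integer seed.
#' @param id character label (e.g. structure id).
#' @return integer sub-seed.
#' @export
subSeed <- function(seed, id) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(id)))
    h <- (h * 31 + code) %% m
  as.integer(h)
}

#' Read a study manifest (TSV)
#'
#' Columns: `structure_path`, `chain`, `conformation`, `gene`,
#' `mutation_table_path`, `fasta_path`, `reconciliation_mode`. Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return data.frame with resolved paths and a `structure_id` column.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("structure_path", "chain", "conformation", "gene",
              "mutation_table_path", "fasta_path", "reconciliation_mode")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop("manifest is empty")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p),
                                p, file.path(base, p))
  df$structure_path <- resolve(df$structure_path)
  df$mutation_table_path <- resolve(df$mutation_table_path)
  df$fasta_path <- resolve(df$fasta_path)
  df$structure_id <- sub("\\.[^.]*$", "", basename(df$structure_path))
  df
}

analyzeManifestRow <- function(row, radii, maxSpheres, T, seed,
                               identityFloor) {
  model <- readStructure(row$structure_path, chain = row$chain,
                         conformation = row$conformation)
  records <- filterMutations(readMutations(row$mutation_table_path))
  canonicalSeq <- if (!is.na(row$fasta_path) && nzchar(row$fasta_path) &&
                      file.exists(row$fasta_path))
    readFastaSequence(row$fasta_path) else NULL
  mapping <- reconcile(canonicalSeq, model, mode = row$reconciliation_mode,
                       identityFloor = identityFloor)
  tally <- suppressMessages(
    tallyMutations(records, mapping, model, canonicalSeq))
  list(model = model, tally = tally,
       result = if (isBlank(tally)) NULL else
         analyzeTally(model, tally, radii = radii, maxSpheres = maxSpheres,
                      T = T, seed = subSeed(seed, row$structure_id)))
}

#' Run a hotspot study over a manifest of structures
#'
#' Analyzes every structure/mutation pair in the manifest, excludes blank
#' structures (fewer than two mapped mutation occurrences) before counting k,
#' and flags significance against the rough-FDR threshold
#' `rfdrThreshold(alpha, k)`, rounded DOWN at `roundDigits` decimals to be
#' conservative. Floored p-values ("< 1/T") are compared as 1/(2T) for
#' thresholding. Per-structure failures are recorded in the row status and do
#' not abort the study. Each structure gets a deterministic sub-seed derived
#' from the master seed and its id, so results do not depend on manifest
#' order.
#'
#' @param manifest path to a manifest TSV (see [readManifest()]) or an
#'   equivalent data.frame.
#' @param alpha nominal level (default 0.05).
#' @param radii radii grid (default 1..10 Angstrom).
#' @param maxSpheres maximum sphere count (default 3).
#' @param T null simulations per structure (default 1000).
#' @param seed master seed (default 1).
#' @param identityFloor alignment identity floor (default 0.90).
#' @param roundDigits decimals to round the threshold down to (default 3).
#' @return a [StudyResult-class].
#' @export
runStudy <- function(manifest, alpha = 0.05, radii = 1:10, maxSpheres = 3L,
                     T = 1000L, seed = 1L, identityFloor = 0.90,
                     roundDigits = 3L) {
  df <- if (is.character(manifest)) readManifest(manifest) else manifest
  if (is.null(df$structure_id))
    df$structure_id <- sub("\\.[^.]*$", "", basename(df$structure_path))
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    out <- data.frame(structure_id = row$structure_id, gene = row$gene,
                      status = "ok", n_mapped = NA_integer_,
                      n_dropped = NA_integer_, p_value = NA_real_,
                      p_floor = NA, p_text = NA_character_,
                      best_s = NA_integer_, best_r = NA_real_,
                      centers = NA_character_, covered = NA_real_,
                      significant = NA)
    res <- tryCatch(
      analyzeManifestRow(row, radii, maxSpheres, T, seed, identityFloor),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- paste0("error: ", conditionMessage(res))
    } else {
      out$n_mapped <- totalMutations(res$tally)
      out$n_dropped <- res$tally@nUnmapped
      if (is.null(res$result)) {
        out$status <- "blank"
      } else {
        hr <- res$result
        out$p_value <- pValue(hr)
        out$p_floor <- hr@pFloor
        out$p_text <- hr@pText
        out$best_s <- hr@bestS
        out$best_r <- hr@bestR
        if (hr@hotspots@feasible) {
          out$centers <- paste(hr@hotspots@centerLabels, collapse = ",")
          out$covered <- hr@hotspots@covered
        }
      }
    }
    rows[[i]] <- out
  }
  rows <- do.call(rbind, rows)
  analyzed <- rows$status == "ok"
  k <- sum(analyzed)
  if (k < 1) stop("no analyzable (non-blank) structures in the study")
  rfdr <- rfdrThreshold(alpha, k)
  threshold <- floor(rfdr * 10^roundDigits) / 10^roundDigits
  effP <- ifelse(rows$p_floor %in% TRUE, 1 / (2 * T), rows$p_value)
  rows$significant <- analyzed & !is.na(effP) & effP <= threshold

  aRows <- rows[analyzed, , drop = FALSE]
  effA <- ifelse(aRows$p_floor %in% TRUE, 1 / (2 * T), aRows$p_value)
  perGene <- do.call(rbind, lapply(split(seq_len(nrow(aRows)), aRows$gene),
    function(ix) {
      best <- ix[which.min(effA[ix])]
      data.frame(gene = aRows$gene[best], min_p_value = aRows$p_value[best],
                 p_text = aRows$p_text[best],
                 significant = any(aRows$significant[ix]))
    }))
  rownames(perGene) <- NULL
  new("StudyResult", k = as.integer(k), alpha = alpha, rfdr = rfdr,
      threshold = threshold, rows = rows, perGene = perGene)
}

setMethod("show", "StudyResult", function(object) {
  cat("StudyResult: k =", object@k, "structures; rFDR =",
      format(object@rfdr, digits = 6), "; effective threshold =",
      object@threshold, "\n")
  cat("  significant:", sum(object@rows$significant, na.rm = TRUE),
      "structure(s),", sum(object@perGene$significant), "gene(s)\n")
})
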