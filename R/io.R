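# Readers and writers for the external formats the tool touches: GMT gene
# sets, plain-text query lists, STRING-style edge lists, FASTA sequences,
# embedding tables and the results TSV. All downstream code consumes only
# the domain objects produced here.

#' Read a GMT gene-set file
#'
#' Parses the tab-separated MSigDB GMT dialect: one gene set per line with
#' fields \code{pathway_id <TAB> description <TAB> member1 <TAB> member2 ...}.
#' Duplicate members within a line are collapsed with a warning; duplicate
#' pathway identifiers are an error. Member order is preserved.
#'
#' @param path path to a GMT file.
#' @param name collection name; defaults to the file name without extension.
#' @return A [PathwayCollection-class].
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("P1\tdemo\tG1\tG2\tG3", f)
#' readGMT(f)
#' @export
readGMT <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- character(length(fields))
  descs <- character(length(fields))
  members <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    mem <- f[-(1:2)]
    mem <- mem[nzchar(trimws(mem))]
    if (length(f) < 3L || !length(mem)) {
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated ",
           "fields with at least one member")
    }
    if (anyDuplicated(mem)) {
      warning("duplicate members collapsed in pathway '", f[1L],
              "' (line ", i, ")")
      mem <- mem[!duplicated(mem)]
    }
    ids[i] <- f[1L]
    descs[i] <- f[2L]
    members[[i]] <- mem
  }
  if (anyDuplicated(ids)) {
    stop("duplicate pathway identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  PathwayCollection(name, ids, members, descs)
}

#' Write a collection to GMT
#'
#' Inverse of [readGMT()]: \code{readGMT(writeGMT(x, f))} reproduces the
#' membership lists exactly for well-formed input.
#'
#' @param collection a [PathwayCollection-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "PathwayCollection"))
  lines <- vapply(seq_along(collection@pathwayIds), function(i) {
    paste(c(collection@pathwayIds[i], collection@descriptions[i],
            collection@members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a query gene/protein list
#'
#' One identifier per line; blank lines and lines starting with \code{#} are
#' skipped; surrounding whitespace is stripped; duplicates are dropped with a
#' warning.
#'
#' @param path path to a plain-text file.
#' @param label query label; defaults to the file name without extension.
#' @return A [GeneQuery-class].
#' @export
readQueryList <- function(path, label = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (!length(ids)) stop("empty query: no identifiers in ", path)
  if (anyDuplicated(ids)) {
    warning("dropped ", sum(duplicated(ids)), " duplicate identifier(s)")
    ids <- ids[!duplicated(ids)]
  }
  GeneQuery(ids, label = label)
}

#' Read a STRING-style interaction edge list
#'
#' Whitespace-separated columns \code{protein1 protein2 combined_score}; a
#' header line whose first token is \code{protein1} is skipped. Edges below
#' \code{minScore} and self-loops are excluded, and symmetric duplicates are
#' merged keeping the maximum score.
#'
#' @param path path to the edge file.
#' @param minScore minimum combined score to retain an edge (default 0:
#'   keep every referenced interaction).
#' @return A [PPIEdges-class].
#' @export
readStringEdges <- function(path, minScore = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge file: ", path)
  offset <- 0L
  if (startsWith(trimws(lines[1L]), "protein1")) {
    lines <- lines[-1L]
    offset <- 1L
  }
  if (!length(lines)) stop("no edges in ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) < 3L)
  if (length(bad)) {
    stop("malformed edge line ", bad[1L] + offset, ": expected 3 columns")
  }
  a <- vapply(toks, `[`, "", 1L)
  b <- vapply(toks, `[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
  if (anyNA(s)) {
    stop("non-numeric combined_score on line ", which(is.na(s))[1L] + offset)
  }
  keep <- s >= minScore
  if (!any(keep & a != b)) {
    warning("no edges passed the score threshold in ", path)
    return(new("PPIEdges", protA = character(), protB = character(),
               score = numeric()))
  }
  PPIEdges(a[keep], b[keep], s[keep])
}

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read protein sequences from FASTA
#'
#' The header token up to the first whitespace is the identifier. Sequences
#' are upper-cased; residues outside the 20 canonical amino acids are
#' replaced by \code{X} with a warning. Duplicate identifiers and empty
#' sequences are errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector: identifier -> amino-acid sequence.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aset <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aset))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aset))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  pat <- paste0("[^", paste(c(.AA_ALPHABET, "X"), collapse = ""), "]")
  nonstd <- grepl(pat, seqs)
  if (any(nonstd)) {
    warning("non-canonical residues replaced by X in ",
            sum(nonstd), " sequence(s)")
    seqs[nonstd] <- gsub(pat, "X", seqs[nonstd])
  }
  stats::setNames(unname(seqs), ids)
}

#' Read / write a protein embedding table
#'
#' Headerless TSV: first column the protein identifier, remaining columns a
#' constant number (>= 3) of numeric embedding coordinates. Values are
#' written at full double precision so write-then-read is an exact
#' round-trip.
#'
#' @param path file path.
#' @return [ProteinEmbeddings-class] for the reader; \code{path} (invisibly)
#'   for the writer.
#' @examples
#' emb <- ProteinEmbeddings(matrix(rnorm(9), 3, 3,
#'                          dimnames = list(c("A", "B", "C"), NULL)))
#' f <- tempfile(fileext = ".tsv")
#' writeEmbeddingTable(emb, f)
#' all.equal(embeddingMatrix(readEmbeddingTable(f)), embeddingMatrix(emb))
#' @export
readEmbeddingTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty table: ", path)
  toks <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(toks)
  if (length(unique(widths)) != 1L) {
    stop("ragged rows in embedding table: widths ",
         paste(sort(unique(widths)), collapse = ", "))
  }
  d <- widths[1L] - 1L
  if (d < 3L) stop("embedding dimension must be at least 3, got ", d)
  ids <- vapply(toks, `[`, "", 1L)
  vals <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[-1L]), numeric(d))
  )
  if (anyNA(vals)) stop("non-numeric embedding value in ", path)
  m <- t(vals)
  rownames(m) <- ids
  ProteinEmbeddings(m)
}

#' @rdname readEmbeddingTable
#' @param table a [ProteinEmbeddings-class].
#' @export
writeEmbeddingTable <- function(table, path) {
  stopifnot(is(table, "ProteinEmbeddings"))
  m <- table@embeddings
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write per-pathway enrichment results to TSV
#'
#' Columns: pathway_id, pathway_size, overlap, coverage, interactions,
#' score, pvalue, bh. Rows are sorted by ascending BH-adjusted p-value, then
#' ascending p-value, then descending score, with pathway_id as the
#' deterministic tie-break; unassessed (NA) p-values sort last.
#'
#' @param results an [EnrichmentTable-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEnrichmentResults <- function(results, path) {
  stopifnot(is(results, "EnrichmentTable"))
  tab <- results@table
  if (!nrow(tab)) stop("no results to write")
  o <- order(tab$bh, tab$pvalue, -tab$score, tab$pathway_id,
             na.last = TRUE)
  cols <- c("pathway_id", "pathway_size", "overlap", "coverage",
            "interactions", "score", "pvalue", "bh")
  utils::write.table(tab[o, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
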