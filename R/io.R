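# Standard-format I/O. FASTA goes through Biostrings and GFF3 through
# rtracklayer; the GenBank flat-file reader/writer is implemented here and is
# lossless for AnnSeq objects (residues, topology, features, qualifiers).
# External files are 1-based inclusive; everything internal stays 0-based
# half-open.

GB_KEY <- c(exon = "exon", cds_segment = "CDS", critical_exon = "exon",
            homology_arm = "misc_feature", recomb_site = "misc_recomb",
            restriction_site = "misc_feature", cassette = "misc_feature",
            primer_site = "primer_bind", promoter = "promoter",
            polyA = "polyA_signal", splice_acceptor = "misc_feature",
            origin = "rep_origin", marker = "misc_feature")

encodeQual <- function(v) {
  if (is.logical(v)) paste0("l:", v)
  else if (is.integer(v)) paste0("i:", v)
  else if (is.numeric(v)) paste0("d:", format(v, digits = 15))
  else paste0("c:", v)
}

decodeQual <- function(s) {
  type <- substr(s, 1, 1)
  v <- substr(s, 3, nchar(s))
  switch(type, l = as.logical(v), i = as.integer(v), d = as.numeric(v), v)
}

#' Write an AnnSeq as a GenBank flat file
#'
#' Feature kinds map onto conventional GenBank keys; the exact internal kind
#' and typed qualifiers are stored in `/tf_*` qualifiers so that
#' [readGenBank()] round-trips losslessly.
#'
#' @param x An [AnnSeq-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(x, path) {
  L <- annLength(x)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (x@topology == "circular") "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN",
                     substr(x@id, 1, 16), L, topo), con)
  writeLines(sprintf("DEFINITION  %s", x@id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- x@features
  if (nrow(f)) for (i in seq_len(nrow(f))) {
    if (f$wrap[i]) {
      loc <- sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, L, f$end[i])
    } else {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    }
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", GB_KEY[[f$kind[i]]], loc), con)
    writeLines(sprintf("                     /label=\"%s\"", f$label[i]), con)
    writeLines(sprintf("                     /tf_kind=\"%s\"", f$kind[i]), con)
    q <- f$quals[[i]]
    for (k in names(q))
      writeLines(sprintf("                     /tf_q_%s=\"%s\"", k,
                         encodeQual(q[[k]])), con)
  }
  writeLines("ORIGIN", con)
  i <- 1L
  while (i <= L) {
    chunk <- substr(x@residues, i, min(i + 59L, L))
    sub <- substring(chunk, seq(1, nchar(chunk), 10),
                     pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, tolower(paste(sub, collapse = " "))),
               con)
    i <- i + 60L
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by [writeGenBank()]
#'
#' @param path GenBank file path.
#' @return An [AnnSeq-class].
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("malformed GenBank record: no LOCUS line in '",
                           path, "'")
  topo <- if (grepl("circular", locus[1])) "circular" else "linear"
  id <- sub("^DEFINITION\\s+", "", grep("^DEFINITION", lines,
                                        value = TRUE)[1])
  if (is.na(id)) id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus[1])),
                                "\\s+")[[1]][1]
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("malformed GenBank record: no ORIGIN in '",
                            path, "'")
  seqlines <- lines[seq(ostart[1] + 1L, length(lines))]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  res <- toupper(gsub("[^a-zA-Z]", "", paste(seqlines, collapse = "")))
  feats <- emptyFeatures()
  if (length(fstart)) {
    flines <- lines[seq(fstart[1] + 1L, ostart[1] - 1L)]
    cur <- NULL
    rows <- list()
    flush <- function(cur) {
      if (is.null(cur)) return(invisible())
      kind <- cur$q[["tf_kind"]] %||% "marker"
      quals <- cur$q[grep("^tf_q_", names(cur$q))]
      if (length(quals)) {
        names(quals) <- sub("^tf_q_", "", names(quals))
        quals <- lapply(quals, decodeQual)
      } else quals <- list()
      rows[[length(rows) + 1L]] <<- data.frame(
        label = cur$q[["label"]] %||% "feature", kind = kind,
        start = cur$start, end = cur$end, strand = cur$strand,
        wrap = cur$wrap, quals = I(list(quals)), stringsAsFactors = FALSE)
      invisible()
    }
    for (ln in flines) {
      if (grepl("^     \\S", ln)) {          # new feature line
        flush(cur)
        loc <- trimws(sub("^     \\S+\\s*", "", ln))
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        wrap <- FALSE
        if (grepl("^join\\(", loc)) {
          wrap <- TRUE
          parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc),
                            ",")[[1]]
          a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
          b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
          start <- a[1] - 1L; end <- b[2]
        } else {
          ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
          start <- ab[1] - 1L; end <- ab[2]
        }
        if (anyNA(c(start, end)))
          stop("malformed GenBank feature location: '", ln, "'")
        cur <- list(start = start, end = end, strand = strand,
                    wrap = wrap, q = list())
      } else if (grepl("^\\s+/", ln)) {
        kv <- sub("^\\s+/", "", ln)
        key <- sub("=.*$", "", kv)
        val <- sub("^[^=]*=", "", kv)
        val <- gsub("^\"|\"$", "", val)
        if (!is.null(cur)) cur$q[[key]] <- val
      }
    }
    flush(cur)
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  AnnSeq(res, id = id, topology = topo, features = sortFeatures(feats))
}

#' Write/read residues as FASTA
#'
#' @param x An [AnnSeq-class] (features are not representable in FASTA).
#' @param path File path.
#' @return `writeFasta` returns `path` invisibly; `readFasta` returns an
#'   [AnnSeq-class] with an empty feature table.
#' @export
writeFasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x@residues)
  names(set) <- x@id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname writeFasta
#' @export
readFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("no records in FASTA '", path, "'")
  AnnSeq(as.character(set[[1]]), id = sub("\\s.*$", "", names(set)[1]))
}

#' Write a gene model as GFF3
#'
#' Emits gene/exon/CDS rows (1-based inclusive, per the GFF3 convention) onto
#' the locus sequence name.
#'
#' @param gene A [GeneModel-class].
#' @param seqid Name of the carrying sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelGFF3 <- function(gene, seqid, path) {
  mk <- function(df, type) {
    if (!nrow(df)) return(NULL)
    GenomicRanges::GRanges(seqid,
                           IRanges::IRanges(df$start + 1L, df$end),
                           strand = gene@strand, type = type,
                           ID = paste0(gene@geneID, "_", type,
                                       seq_len(nrow(df))))
  }
  gr <- c(GenomicRanges::GRanges(seqid,
                                 IRanges::IRanges(min(gene@exons$start) + 1L,
                                                  max(gene@exons$end)),
                                 strand = gene@strand, type = "gene",
                                 ID = gene@geneID),
          mk(gene@exons, "exon"), mk(gene@cds, "CDS"))
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' @param path GFF3 path (exon and CDS rows are used).
#' @param geneID Gene identifier to assign.
#' @param expressionPctTrfr,essentialInES Model annotations not representable
#'   in GFF3.
#' @return A [GeneModel-class].
#' @export
readGeneModelGFF3 <- function(path, geneID = NULL, expressionPctTrfr = 10,
                              essentialInES = FALSE) {
  gr <- rtracklayer::import(path, format = "gff3")
  take <- function(type) {
    g <- gr[gr$type == type]
    g <- g[order(BiocGenerics::start(g))]
    data.frame(start = BiocGenerics::start(g) - 1L,
               end = BiocGenerics::end(g))
  }
  ex <- take("exon"); cd <- take("CDS")
  if (!nrow(ex)) stop("GFF3 '", path, "' carries no exon rows")
  strand <- as.character(BiocGenerics::strand(gr[gr$type == "exon"]))[1]
  if (!strand %in% c("+", "-")) strand <- "+"
  if (is.null(geneID)) {
    g <- gr[gr$type == "gene"]
    geneID <- if (length(g) && !is.null(g$ID)) g$ID[1] else "gene"
  }
  GeneModel(geneID, strand = strand, exons = ex, cds = cd,
            expressionPctTrfr = expressionPctTrfr,
            essentialInES = essentialInES)
}
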