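#' Read a gene-table TSV
#'
#' Reads the documented tab-separated annotation dialect: required columns
#' `gene`, `kind`, `start`, `stop`, `strand`, optional `anticodon`; integer
#' coordinates without thousands separators; strand symbols `+` and `-`
#' (a Unicode minus is tolerated). Unknown columns are ignored with a
#' warning. The result is a table-only [mitogenome()] unless a sequence is
#' supplied.
#'
#' @param path Path to the TSV file.
#' @param genome_length Optional declared genome length; inferred as the
#'   maximum `stop` coordinate when absent.
#' @param taxon,accession Metadata to attach.
#' @return A table-only [mitogenome()].
#' @examples
#' tbl <- system.file("extdata", "selene_dorsalis_table1.tsv",
#'                    package = "mitoprofile")
#' g <- read_gene_table(tbl)
#' genome_length(g)  # 16541
#' @export
read_gene_table <- function(path, genome_length = NULL, taxon = "",
                            accession = "") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("gene", "kind", "start", "stop", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(need, "anticodon"))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  mitogenome(df, genome_length = genome_length, taxon = taxon,
             accession = accession)
}

#' Write a gene table as TSV
#'
#' @param genome A [mitogenome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genome, path) {
  df <- genome$genes[, c("gene", "kind", "start", "stop", "strand", "anticodon")]
  df$anticodon[is.na(df$anticodon)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged African moonfish annotation table
#'
#' Loads the annotation table of the Selene dorsalis mitogenome (GenBank
#' PP857611) shipped with the package: 38 features (13 PCGs, 22 tRNAs,
#' 2 rRNAs, control region) on a 16,541 bp circular genome. This is a
#' table-only genome; the sequence itself is obtained from GenBank by the
#' user when composition statistics on the real genome are wanted.
#'
#' @return A table-only [mitogenome()].
#' @export
selene_table1 <- function() {
  read_gene_table(
    system.file("extdata", "selene_dorsalis_table1.tsv",
                package = "mitoprofile", mustWork = TRUE),
    taxon = "Selene dorsalis", accession = "PP857611"
  )
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings. `read_alignment()` additionally enforces
#' equal sequence lengths.
#'
#' @param path File path.
#' @return Named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
read_alignment <- function(path) {
  x <- read_fasta(path)
  if (length(unique(nchar(x))) > 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(nchar(x)), collapse = ", "))
  }
  x
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# ---- gene-name normalization -------------------------------------------

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")

GENE_SYNONYMS <- c(
  COX1 = "COI", COXI = "COI", CO1 = "COI", COI = "COI",
  COX2 = "COII", COXII = "COII", CO2 = "COII", COII = "COII",
  COX3 = "COIII", COXIII = "COIII", CO3 = "COIII", COIII = "COIII",
  COB = "CYTB", CYB = "CYTB", CYTB = "CYTB",
  NAD1 = "ND1", ND1 = "ND1", NAD2 = "ND2", ND2 = "ND2",
  NAD3 = "ND3", ND3 = "ND3", NAD4 = "ND4", ND4 = "ND4",
  NAD4L = "ND4L", ND4L = "ND4L", NAD5 = "ND5", ND5 = "ND5",
  NAD6 = "ND6", ND6 = "ND6",
  ATP6 = "ATP6", ATPASE6 = "ATP6", ATP8 = "ATP8", ATPASE8 = "ATP8",
  RRNS = "12S-rRNA", RRN12 = "12S-rRNA", `12S` = "12S-rRNA",
  `12S-RRNA` = "12S-rRNA", `S-RRNA` = "12S-rRNA",
  RRNL = "16S-rRNA", RRN16 = "16S-rRNA", `16S` = "16S-rRNA",
  `16S-RRNA` = "16S-rRNA", `L-RRNA` = "16S-rRNA",
  `D-LOOP` = "CR", DLOOP = "CR", `CONTROL REGION` = "CR", CR = "CR"
)

#' Normalize a mitochondrial gene name
#'
#' Maps the inconsistent gene/product labels found in GenBank records
#' (`COX1`, `cob`, `rrnS`, `12S ribosomal RNA`, `tRNA-Phe`, `trnF`, ...) to
#' the canonical symbols used by this package. Unknown names pass through
#' unchanged with a warning.
#'
#' @param name Character vector of raw names.
#' @return Character vector of canonical names.
#' @export
normalize_gene_name <- function(name) {
  vapply(name, function(nm) {
    key <- toupper(trimws(nm))
    key <- sub("\\s+GENE$", "", key)
    if (grepl("RIBOSOMAL", key)) {
      if (grepl("12S|SMALL", key)) return("12S-rRNA")
      if (grepl("16S|LARGE", key)) return("16S-rRNA")
    }
    if (key %in% names(GENE_SYNONYMS)) return(unname(GENE_SYNONYMS[key]))
    # tRNA-Xxx or trnX forms; serine/leucine isoacceptors keep their suffix
    m <- regmatches(key, regexec("^TRNA[- ]([A-Z]{3})\\s*\\(?(S1|S2|L1|L2)?\\)?$", key))[[1]]
    if (length(m)) {
      aa <- paste0(substr(m[2], 1, 1), tolower(substr(m[2], 2, 3)))
      if (aa %in% names(AA3)) {
        return(paste0("tRNA-", aa, if (nzchar(m[3])) paste0("(", m[3], ")") else ""))
      }
    }
    m <- regmatches(key, regexec("^TRN([A-Z])([0-9])?$", key))[[1]]
    if (length(m)) {
      aa <- names(AA3)[match(m[2], AA3)]
      if (!is.na(aa)) {
        return(paste0("tRNA-", aa, if (nzchar(m[3])) paste0("(", substr(aa, 1, 1), m[3], ")") else ""))
      }
    }
    warning("unrecognized gene name kept as-is: ", nm)
    nm
  }, character(1), USE.NAMES = FALSE)
}

# ---- GenBank flat file --------------------------------------------------

#' Read a GenBank flat file
#'
#' Minimal reader for single-record GenBank flat files of annotated
#' mitogenomes: parses LOCUS (length, circular/linear), ACCESSION,
#' ORGANISM, the feature table (CDS, tRNA, rRNA, D-loop and
#' control-region misc_features) and the ORIGIN sequence. `complement(..)`
#' locations become light-strand records; `join(..)` locations spanning the
#' origin of a circular record become wrap-around coordinates. Gene names
#' are canonicalized with [normalize_gene_name()].
#'
#' @param path Path to a GenBank flat file.
#' @return A [mitogenome()] with sequence.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file: no LOCUS line")
  circular <- grepl("circular", locus[1], ignore.case = TRUE)
  acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
             grep("^ACCESSION", lines, value = TRUE)[1])
  if (is.na(acc)) acc <- ""
  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  taxon <- if (length(org)) trimws(sub("^\\s+ORGANISM\\s+", "", org[1])) else ""

  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("GenBank record lacks an ORIGIN sequence block")
  oend <- grep("^//", lines)
  oend <- oend[oend > ostart[1]][1]
  if (is.na(oend)) oend <- length(lines) + 1L
  seq_lines <- lines[(ostart[1] + 1L):(oend - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  L <- nchar(sequence)

  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("GenBank record lacks a FEATURES table")
  feat_lines <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
  is_key <- grepl("^ {5}\\S", feat_lines)
  idx <- which(is_key)
  recs <- list()
  for (j in seq_along(idx)) {
    block <- feat_lines[idx[j]:(if (j < length(idx)) idx[j + 1L] - 1L else length(feat_lines))]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   `D-loop` = "CR", misc_feature = "misc", NA_character_)
    if (is.na(kind)) next
    loc <- sub("^ {5}\\S+\\s+", "", block[1])
    # continuation lines of the location (no qualifiers yet)
    k <- 2L
    while (k <= length(block) && !grepl("^\\s+/", block[k])) {
      loc <- paste0(loc, trimws(block[k])); k <- k + 1L
    }
    quals <- paste(block[seq.int(k, length.out = max(0L, length(block) - k + 1L))],
                   collapse = " ")
    get_q <- function(q) {
      m <- regmatches(quals, regexec(paste0("/", q, '="([^"]*)"'), quals))[[1]]
      if (length(m)) m[2] else NA_character_
    }
    gene <- get_q("gene"); product <- get_q("product"); note <- get_q("note")
    if (kind == "misc") {
      txt <- tolower(paste(gene, product, note))
      if (!grepl("control region|d-loop", txt)) next
      kind <- "CR"
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    loc2 <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
    loc2 <- gsub("[<>]", "", loc2)
    parts <- strsplit(loc2, ",")[[1]]
    bounds <- lapply(strsplit(parts, "\\.\\."), as.integer)
    a <- bounds[[1]][1]
    b <- bounds[[length(bounds)]][length(bounds[[length(bounds)]])]
    if (length(bounds) > 1L) {
      # join spanning the origin: first segment must end at L, next start at 1
      if (!(circular && bounds[[1]][2] == L && bounds[[2]][1] == 1L)) {
        stop("unsupported join location: ", loc)
      }
    }
    if (max(unlist(bounds)) > L) stop("feature beyond sequence length: ", loc)
    if (b < a && length(bounds) == 1L) stop("reversed location on a linear span: ", loc)
    nm <- if (kind == "CR") "CR" else {
      raw <- if (!is.na(gene)) gene else if (!is.na(product)) product else key
      normalize_gene_name(raw)
    }
    recs[[length(recs) + 1L]] <- data.frame(
      gene = nm, kind = kind, start = a, stop = b, strand = strand,
      anticodon = toupper(get_q("anticodon")), stringsAsFactors = FALSE
    )
  }
  if (!length(recs)) stop("no usable features in GenBank record")
  genes <- do.call(rbind, recs)
  mitogenome(genes, sequence = sequence, taxon = taxon, accession = acc,
             circular = circular)
}

#' Write a GenBank flat file
#'
#' Emits a minimal but syntactically valid single-record flat file
#' (LOCUS/ACCESSION/FEATURES/ORIGIN) that [read_genbank()] round-trips.
#'
#' @param genome A [mitogenome()] with sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  if (is.null(genome$sequence)) stop("cannot write GenBank without a sequence")
  L <- genome$genome_length
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %-16s %d bp    DNA     %s VRT",
     if (nzchar(genome$accession)) genome$accession else "UNNAMED", L,
     if (genome$circular) "circular" else "linear")
  wl("DEFINITION  %s mitochondrion, complete genome.",
     if (nzchar(genome$taxon)) genome$taxon else "synthetic construct")
  wl("ACCESSION   %s", if (nzchar(genome$accession)) genome$accession else ".")
  wl("SOURCE      %s", genome$taxon)
  wl("  ORGANISM  %s", genome$taxon)
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", L)
  for (i in seq_len(nrow(genome$genes))) {
    r <- genome$genes[i, ]
    key <- switch(r$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
    loc <- if (r$stop >= r$start) sprintf("%d..%d", r$start, r$stop)
           else sprintf("join(%d..%d,1..%d)", r$start, L, r$stop)
    if (r$strand == "-") loc <- sprintf("complement(%s)", loc)
    wl("     %-15s %s", key, loc)
    wl("                     /gene=\"%s\"", r$gene)
    if (!is.na(r$anticodon) && nzchar(r$anticodon)) {
      wl("                     /anticodon=\"%s\"", r$anticodon)
    }
  }
  wl("ORIGIN")
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(genome$sequence, off, min(off + 59L, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl("%9d %s", off, tolower(paste(groups, collapse = " ")))
  }
  wl("//")
  invisible(path)
}
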