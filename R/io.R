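# BEDPE and TSV readers/writers.  BEDPE is written 0-based half-open with
# the standard ten columns plus svclass, caller and precise.

BEDPE_COLS <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                "name", "score", "strand1", "strand2", "svclass", "caller",
                "precise")

#' Write SV calls as BEDPE
#'
#' @param calls SV data.frame (columns chrom1, pos1, chrom2, pos2,
#'   sv_class, orient1, orient2, support, caller, precise).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  df <- data.frame(chrom1 = calls$chrom1, start1 = calls$pos1,
                   end1 = calls$pos1 + 1L,
                   chrom2 = calls$chrom2, start2 = calls$pos2,
                   end2 = calls$pos2 + 1L,
                   name = if (!is.null(calls$name)) calls$name
                          else sprintf("sv%04d", seq_len(nrow(calls))),
                   score = calls$support,
                   strand1 = calls$orient1, strand2 = calls$orient2,
                   svclass = calls$sv_class, caller = calls$caller,
                   precise = calls$precise,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Load SV calls from BEDPE
#'
#' Accepts the dialect written by [write_bedpe()] (>= 10 columns, with or
#' without a header line).  Malformed rows are reported with their line
#' numbers; an intra-chromosomal row labeled TRA (or an inter-chromosomal
#' row labeled otherwise) is rejected as a class/chromosome inconsistency.
#'
#' @param path BEDPE path.
#' @return SV data.frame (chrom1, pos1, chrom2, pos2, sv_class, orient1,
#'   orient2, support, caller, precise).
#' @export
load_bedpe <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  has_header <- length(lines) > 0 && grepl("^chrom1\t", lines[1])
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  empty <- new_sv_call("chr0", 0, "chr0", 1, "DEL")[0, ]
  if (!length(body)) return(empty)
  rows <- lapply(seq_along(body), function(i) {
    lineno <- i + offset
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10) {
      stop("line ", lineno, ": expected >= 10 tab-separated columns, got ",
           length(f))
    }
    pos <- suppressWarnings(as.integer(f[c(2, 5)]))
    if (any(is.na(pos))) {
      stop("line ", lineno, ": unparseable coordinate '",
           paste(f[c(2, 5)], collapse = "', '"), "'")
    }
    svclass <- if (length(f) >= 11) f[11] else NA_character_
    if (is.na(svclass) || !svclass %in% c("DEL", "DUP", "INV", "TRA")) {
      stop("line ", lineno, ": unknown sv_class token '", svclass, "'")
    }
    if ((svclass == "TRA") != (f[1] != f[4])) {
      stop("line ", lineno, ": sv_class ", svclass,
           " inconsistent with chromosomes ", f[1], "/", f[4])
    }
    data.frame(chrom1 = f[1], pos1 = pos[1], chrom2 = f[4], pos2 = pos[2],
               sv_class = svclass, orient1 = f[9], orient2 = f[10],
               support = suppressWarnings(as.integer(f[8])),
               caller = if (length(f) >= 12) f[12] else NA_character_,
               precise = if (length(f) >= 13) as.logical(f[13]) else FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the windowed depth table
#' @param depth data.frame(chrom, window_start, tumor_count, control_count).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a windowed depth table
#' @param path TSV with columns chrom, window_start, tumor_count,
#'   control_count.
#' @return data.frame.
#' @export
read_depth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write junction consensus sequences
#'
#' Two-column TSV (sv_id, sequence) plus a FASTA with the same records.
#'
#' @param truths List of `sv_truth` records (or a [truth_table()]).
#' @param tsv_path,fasta_path Output paths (either may be NULL).
#' @return Invisibly, the truth table used.
#' @export
write_junctions <- function(truths, tsv_path = NULL, fasta_path = NULL) {
  tab <- if (is.data.frame(truths)) truths else truth_table(truths)
  tab <- tab[!is.na(tab$junction_sequence), , drop = FALSE]
  if (!is.null(tsv_path)) {
    utils::write.table(tab[, c("sv_id", "junction_sequence")], tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("sv_id", "sequence"))
  }
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(tab$junction_sequence)
    names(x) <- tab$sv_id
    Biostrings::writeXStringSet(x, filepath = fasta_path)
  }
  invisible(tab)
}

#' Write a full simulated study to a directory
#'
#' Emits the genome FASTA, per-caller tumor BEDPE files, the control BEDPE,
#' the truth table TSV, junction TSV/FASTA and the depth TSV.
#'
#' @param study Result of [simulate_rearrangement_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(study$genome, file.path(dir, "genome.fa"))
  for (caller in names(study$caller_output$tumor)) {
    write_bedpe(study$caller_output$tumor[[caller]],
                file.path(dir, paste0("tumor_", caller, ".bedpe")))
  }
  write_bedpe(study$caller_output$control, file.path(dir, "control.bedpe"))
  tab <- truth_table(c(study$truths, study$germline_truths))
  utils::write.table(tab, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_junctions(tab, tsv_path = file.path(dir, "junctions.tsv"),
                  fasta_path = file.path(dir, "junctions.fa"))
  write_depth_tsv(study$depth, file.path(dir, "depth.tsv"))
  invisible(dir)
}
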