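# Representation of engineered LCD2-CTPR constructs: ordered segments,
# per-residue domain annotation, and mapping of atomistic structures to
# one-bead-per-residue coarse-grained chains.

.SEGMENT_KINDS <- c("LCD2_N", "REPEAT", "TC_LOOP", "LIR_LINKER",
                    "SOLVATING_HELIX", "LCD2_C", "OTHER_LOOP")
.RIGID_KINDS <- c("REPEAT", "SOLVATING_HELIX")

#' Create a construct segment
#'
#' A segment is a contiguous stretch of sequence with a structural role:
#' the disordered N-/C-terminal low-complexity domains (`LCD2_N`, `LCD2_C`),
#' folded 34-residue consensus TPR repeats (`REPEAT`), the C-terminal
#' solvating helix (`SOLVATING_HELIX`), functional inter-repeat loops
#' carrying LC3-interacting motifs (`LIR_LINKER`), tetracysteine-tag loops
#' (`TC_LOOP`), and any other loop (`OTHER_LOOP`). Only `REPEAT` and
#' `SOLVATING_HELIX` segments are treated as rigid in coarse-grained models.
#'
#' @param kind Segment kind, one of
#'   `r paste0('\x60', .SEGMENT_KINDS, '\x60', collapse = ", ")`.
#' @param sequence Non-empty one-letter amino-acid string.
#' @return A `construct_segment` list with `kind`, `sequence`, `length`,
#'   `rigid`.
#' @export
construct_segment <- function(kind, sequence) {
  kind <- match.arg(kind, .SEGMENT_KINDS)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  residue_masses(sequence)  # validates alphabet, errors with position
  structure(
    list(kind = kind, sequence = toupper(sequence),
         length = nchar(sequence), rigid = kind %in% .RIGID_KINDS),
    class = "construct_segment"
  )
}

#' Assemble a construct from ordered segments
#'
#' Concatenates segment sequences in order into a full construct
#' specification. Every residue belongs to exactly one segment; total length
#' is the sum of segment lengths.
#'
#' @param segments List of [construct_segment()] objects (or plain lists with
#'   `kind` and `sequence`), in N-to-C order.
#' @param name Construct identifier.
#' @return A `construct_spec` with fields `name`, `segments`, `sequence`,
#'   `length`.
#' @export
#' @examples
#' sp <- assemble_construct(list(construct_segment("LCD2_N", "GSYGQ")), "mini")
#' sp$length
assemble_construct <- function(segments, name = "construct") {
  stopifnot(length(segments) >= 1L)
  segments <- lapply(segments, function(s) {
    if (inherits(s, "construct_segment")) s
    else construct_segment(s$kind, s$sequence)
  })
  offset <- 0L
  for (i in seq_along(segments)) {
    aa <- strsplit(segments[[i]]$sequence, "")[[1]]
    bad <- which(!aa %in% .AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("non-standard residue '", aa[bad[1L]], "' at position ",
           offset + bad[1L], " of construct '", name, "'")
    }
    segments[[i]]$start <- offset + 1L
    segments[[i]]$end <- offset + segments[[i]]$length
    offset <- offset + segments[[i]]$length
  }
  full <- paste(vapply(segments, `[[`, character(1L), "sequence"),
                collapse = "")
  structure(
    list(name = name, segments = segments, sequence = full,
         length = nchar(full)),
    class = "construct_spec"
  )
}

#' @export
print.construct_spec <- function(x, ...) {
  cat("construct_spec '", x$name, "': ", x$length, " residues, ",
      length(x$segments), " segments\n", sep = "")
  for (s in x$segments) {
    cat(sprintf("  %-15s %4d-%-4d (%d aa)%s\n", s$kind, s$start, s$end,
                s$length, if (s$rigid) " [rigid]" else ""))
  }
  invisible(x)
}

#' Annotate every residue of a construct with its domain
#'
#' Maps segments to the domain labels used in contact analysis:
#' `LCD2_N`, `LCD2_C`, `REPEAT_k` (k-th repeat, N-to-C), `LINKER`
#' (LIR-carrying loops), and `OTHER` (solvating helix and plain loops).
#' Ranges are 1-based inclusive, non-overlapping, and tile `1..L`.
#'
#' @param spec A [assemble_construct()] result.
#' @return A `region_annotation` with `construct_name`, `labels`
#'   (character vector of length L) and `ranges`
#'   (data.frame `label`, `start`, `end`).
#' @export
annotate_regions <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  repeat_i <- 0L
  labels <- character(spec$length)
  ranges <- list()
  for (s in spec$segments) {
    lab <- switch(s$kind,
      LCD2_N = "LCD2_N",
      LCD2_C = "LCD2_C",
      LIR_LINKER = "LINKER",
      REPEAT = {
        repeat_i <- repeat_i + 1L
        paste0("REPEAT_", repeat_i)
      },
      "OTHER"
    )
    labels[s$start:s$end] <- lab
    ranges[[length(ranges) + 1L]] <-
      data.frame(label = lab, start = s$start, end = s$end,
                 stringsAsFactors = FALSE)
  }
  structure(
    list(construct_name = spec$name, labels = labels,
         ranges = do.call(rbind, ranges)),
    class = "region_annotation"
  )
}

#' Pooled domain labels for contact analysis
#'
#' Collapses `REPEAT_k` to a single `REPEAT` category, matching the pooled
#' "Repeat" category of domain-level contact summaries.
#'
#' @param annotation A [annotate_regions()] result.
#' @return Character vector of length L over
#'   \{LCD2_N, LCD2_C, REPEAT, LINKER, OTHER\}.
#' @export
pooled_labels <- function(annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  sub("^REPEAT_[0-9]+$", "REPEAT", annotation$labels)
}

#' Per-residue rigidity flags of a construct
#'
#' @param spec A `construct_spec`.
#' @return Logical vector of length L; `TRUE` on residues inside REPEAT and
#'   SOLVATING_HELIX segments.
#' @export
rigid_flags <- function(spec) {
  stopifnot(inherits(spec, "construct_spec"))
  out <- logical(spec$length)
  for (s in spec$segments) if (s$rigid) out[s$start:s$end] <- TRUE
  out
}

#' Coarse-grain an atomistic structure to one bead per residue
#'
#' Places one bead at the alpha-carbon of each residue and carries the
#' construct's rigidity flags onto the beads, mirroring the
#' one-bead-per-amino-acid coarse-graining used for slab simulations of
#' these constructs.
#'
#' @param structure Either a data.frame with columns `resno` (1-based residue
#'   index), `elety` (atom name, alpha carbons are `"CA"`), `x`, `y`, `z`
#'   (Angstrom) and optionally `resid` (three-letter residue name), or a
#'   `bio3d` `pdb` object (first model; see [read_structure_pdb()]).
#' @param spec The `construct_spec` the structure realises; the structure's
#'   residue sequence (when available) must match `spec$sequence`.
#' @return A `cg_chain`: `xyz` (L x 3 matrix, Angstrom), `resno`, `rigid`,
#'   `sequence`, `chain_id`.
#' @export
coarse_grain <- function(structure, spec) {
  stopifnot(inherits(spec, "construct_spec"))
  if (inherits(structure, "pdb")) structure <- structure$atom
  stopifnot(is.data.frame(structure))
  need <- c("resno", "elety", "x", "y", "z")
  if (!all(need %in% names(structure))) {
    stop("structure must have columns ", paste(need, collapse = ", "))
  }
  ca <- structure[structure$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]  # first model / altloc
  L <- spec$length
  missing <- setdiff(seq_len(L), ca$resno)
  if (length(missing) > 0L) {
    stop("missing alpha carbon for residue ", missing[1L])
  }
  ca <- ca[match(seq_len(L), ca$resno), , drop = FALSE]
  if ("resid" %in% names(ca)) {
    seq3 <- .aa321(ca$resid)
    if (!all(is.na(seq3))) {
      got <- paste(seq3, collapse = "")
      if (got != spec$sequence) {
        stop("structure sequence does not match construct '", spec$name, "'")
      }
    }
  }
  structure(
    list(xyz = cbind(x = ca$x, y = ca$y, z = ca$z),
         resno = seq_len(L), rigid = rigid_flags(spec),
         sequence = spec$sequence, chain_id = spec$name),
    class = "cg_chain"
  )
}

.AA321_MAP <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.aa321 <- function(resid) {
  unname(.AA321_MAP[toupper(trimws(resid))])
}

#' Read a PDB structure (first model, for coarse-graining)
#'
#' Thin wrapper around `bio3d::read.pdb()`.
#'
#' @param path PDB file.
#' @return A `bio3d` `pdb` object suitable for [coarse_grain()].
#' @export
read_structure_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("package 'bio3d' is required to read PDB files")
  }
  bio3d::read.pdb(path, multi = FALSE)
}

#' Read construct definitions from YAML
#'
#' The file lists named constructs, each an ordered list of segments with a
#' `kind` and either an inline `sequence` or a `fasta` entry naming a record
#' in an accompanying FASTA file.
#'
#' @param path YAML file.
#' @param fasta Optional FASTA file providing sequences referenced by name.
#' @return Named list of `construct_spec` objects.
#' @export
read_constructs_yaml <- function(path, fasta = NULL) {
  doc <- yaml::read_yaml(path)
  stopifnot(!is.null(doc$constructs))
  fasta_seqs <- NULL
  if (!is.null(fasta)) {
    if (!requireNamespace("seqinr", quietly = TRUE)) {
      stop("package 'seqinr' is required to import FASTA sequences")
    }
    fa <- seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE)
    fasta_seqs <- toupper(vapply(fa, `[[`, character(1L), 1L))
    names(fasta_seqs) <- names(fa)
  }
  out <- list()
  for (cdef in doc$constructs) {
    segs <- lapply(cdef$segments, function(s) {
      seqstr <- s$sequence
      if (is.null(seqstr) && !is.null(s$fasta)) {
        if (is.null(fasta_seqs) || !s$fasta %in% names(fasta_seqs)) {
          stop("FASTA record '", s$fasta, "' not found for construct '",
               cdef$name, "'")
        }
        seqstr <- fasta_seqs[[s$fasta]]
      }
      construct_segment(s$kind, seqstr)
    })
    out[[cdef$name]] <- assemble_construct(segs, name = cdef$name)
  }
  out
}

# ---- Named variants ---------------------------------------------------------

.LCD2_MOTIF <- "GSYGQSSYGGQNQGGYGQQSNYGQPQSGSYSQ"
.CTPR_REPEAT <- "AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN"          # 34 aa
.CTPR_REPEAT_R <- "AEAWYNLGNAYYRQGDYDEAIEYYQRALELDPNN"        # K -> R
.SOLV_HELIX <- "AEAKQNLGNAKQKQGDYQKAIEYYQ"
.LOOP_FILL <- "GSGNSTGSGNSTGSGNSTGSGNSTGSG"

.cycle_seq <- function(motif, n) {
  paste(rep(strsplit(motif, "")[[1]], length.out = n), collapse = "")
}

#' Built-in LCD2-CTPR variant definitions (synthetic placeholder sequences)
#'
#' Returns the segment architecture of the six named LCD2-CTPR variants with
#' the published total lengths and domain boundaries: the LCD2 termini span
#' 1-173 and 267-334 (CTPR2), 301-369 (CTPR3 and R-CTPR3), 320-388 (CTPR4),
#' 337-409 (CTPR4-FUNDC1) and 339-411 (CTPR4-ATG13); the LIR linkers span
#' 282-306 (FUNDC1) and 282-308 (ATG13). The segment sequences themselves are
#' synthetic placeholders of the correct lengths (built from the consensus
#' TPR repeat and low-complexity-like filler), adequate for geometry, mass
#' and annotation work but not real published sequences.
#'
#' @param variant One of `"LCD2-CTPR2"`, `"LCD2-CTPR3"`, `"LCD2-R-CTPR3"`,
#'   `"LCD2-CTPR4"`, `"LCD2-CTPR4-FUNDC1"`, `"LCD2-CTPR4-ATG13"`.
#' @return A `construct_spec`.
#' @export
#' @examples
#' sp <- lcd2_ctpr_spec("LCD2-CTPR4")
#' annotate_regions(sp)$ranges
lcd2_ctpr_spec <- function(variant = c("LCD2-CTPR2", "LCD2-CTPR3",
                                       "LCD2-R-CTPR3", "LCD2-CTPR4",
                                       "LCD2-CTPR4-FUNDC1",
                                       "LCD2-CTPR4-ATG13")) {
  variant <- match.arg(variant)
  rep_seq <- if (variant == "LCD2-R-CTPR3") .CTPR_REPEAT_R else .CTPR_REPEAT
  lcd_n <- construct_segment("LCD2_N", .cycle_seq(.LCD2_MOTIF, 173L))
  seg_rep <- function(n = 34L) {
    construct_segment("REPEAT", .cycle_seq(rep_seq, n))
  }
  lcd_c <- function(n) construct_segment("LCD2_C", .cycle_seq(.LCD2_MOTIF, n))
  solv <- function(n) {
    construct_segment("SOLVATING_HELIX", .cycle_seq(.SOLV_HELIX, n))
  }
  lir <- function(n) {
    core <- .cycle_seq(.LOOP_FILL, n - 8L)
    construct_segment("LIR_LINKER", paste0("DPNN", core, "DPNN"))
  }
  loop <- function(n) construct_segment("OTHER_LOOP", .cycle_seq(.LOOP_FILL, n))

  segs <- switch(variant,
    "LCD2-CTPR2" = list(lcd_n, seg_rep(), seg_rep(), solv(25L), lcd_c(68L)),
    "LCD2-CTPR3" = ,
    "LCD2-R-CTPR3" = list(lcd_n, seg_rep(), seg_rep(), seg_rep(), solv(25L),
                          lcd_c(69L)),
    "LCD2-CTPR4" = list(lcd_n, seg_rep(), seg_rep(), seg_rep(), seg_rep(),
                        solv(10L), lcd_c(69L)),
    "LCD2-CTPR4-FUNDC1" = list(lcd_n, seg_rep(), seg_rep(), seg_rep(),
                               loop(6L), lir(25L), seg_rep(30L), lcd_c(73L)),
    "LCD2-CTPR4-ATG13" = list(lcd_n, seg_rep(), seg_rep(), seg_rep(),
                              loop(6L), lir(27L), seg_rep(30L), lcd_c(73L))
  )
  assemble_construct(segs, name = variant)
}
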