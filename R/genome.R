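#' Beads-on-a-string genomes
#'
#' A genome is an ordered list of beads of three kinds: regulatory genes
#' (`"G"`), binding sites (`"B"`) and passive household genes (`"H"`).
#' Genes carry a type label (types 1--5 are the core cell-cycle types
#' g1--g5; larger labels are evolved, non-core types), a binding sequence of
#' `B` bits, a 2-bit signal peptide (first bit: host localization, second
#' bit: symbiont localization), an integer regulatory weight and an integer
#' activation threshold. Binding sites carry only a sequence. Household
#' beads are passive: they count towards genome size `L` (and hence towards
#' replication time) but never towards expression dynamics.
#'
#' Internally a genome is a list of parallel vectors (one element per bead):
#' `kind` (`"H"`, `"B"`, `"G"`), `type_id`, `seq` (integer mask), `sp`
#' (integer 0--3, encoded as `2*host_bit + symbiont_bit`), `weight`,
#' `threshold`. Positions are 1-based; "upstream" means lower positions;
#' replication proceeds from position 1 towards `L`.
#'
#' @param beads a list of beads, each created by [gene_bead()], [site_bead()]
#'   or [household_bead()].
#' @param B bit-vector length for all sequences in the genome.
#' @return an object of class `endo_genome`.
#' @seealso [parse_genome()], [genome_stats()], [regulatory_region()]
#' @export
new_genome <- function(beads = list(), B = 20L) {
  n <- length(beads)
  g <- list(
    kind      = character(n),
    type_id   = rep(NA_integer_, n),
    seq       = rep(NA_integer_, n),
    sp        = rep(NA_integer_, n),
    weight    = rep(NA_integer_, n),
    threshold = rep(NA_integer_, n)
  )
  for (i in seq_len(n)) {
    b <- beads[[i]]
    g$kind[i] <- b$kind
    if (b$kind == "B") {
      g$seq[i] <- b$seq
    } else if (b$kind == "G") {
      g$type_id[i] <- b$type_id
      g$seq[i] <- b$seq
      g$sp[i] <- b$sp
      g$weight[i] <- b$weight
      g$threshold[i] <- b$threshold
    }
  }
  structure(g, B = as.integer(B), class = "endo_genome")
}

#' Bead constructors
#'
#' @param type_id integer gene type (1--5 core, >5 evolved).
#' @param seq sequence as bit string, 0/1 vector, or integer mask.
#' @param sp signal peptide as 2-bit string (`"10"` host, `"01"` symbiont,
#'   `"00"` none, `"11"` dual) or integer 0--3.
#' @param weight signed integer regulatory effect.
#' @param threshold signed integer activation threshold.
#' @return a bead (plain list) for [new_genome()].
#' @export
gene_bead <- function(type_id, seq, sp = "00", weight = 1L, threshold = 0L) {
  list(kind = "G", type_id = as.integer(type_id), seq = as_mask(seq),
       sp = as_sp(sp), weight = as.integer(weight),
       threshold = as.integer(threshold))
}

#' @rdname gene_bead
#' @export
site_bead <- function(seq) list(kind = "B", seq = as_mask(seq))

#' @rdname gene_bead
#' @export
household_bead <- function() list(kind = "H")

as_mask <- function(seq) {
  if (is.character(seq) || length(seq) > 1L) bits_to_mask(seq) else as.integer(seq)
}

as_sp <- function(sp) {
  if (is.character(sp)) {
    stopifnot(nchar(sp) == 2L)
    b <- as.integer(strsplit(sp, "")[[1]])
    return(2L * b[1] + b[2])
  }
  sp <- as.integer(sp)
  stopifnot(sp >= 0L, sp <= 3L)
  sp
}

sp_to_string <- function(sp) paste0(sp %/% 2L, sp %% 2L)

#' @export
length.endo_genome <- function(x) length(x$kind)

#' @export
print.endo_genome <- function(x, ...) {
  s <- genome_stats(x)
  cat(sprintf("<endo_genome> L=%d (R=%d, household=%d), B=%d\n",
              s$L, s$R, s$household_count, attr(x, "B")))
  invisible(x)
}

genome_B <- function(genome) attr(genome, "B")

#' Genome size statistics
#'
#' `L` is the total bead count, `R` the regulatory repertoire (genes plus
#' binding sites, i.e. all non-household beads) and `household_count`
#' the number of passive household beads, so `L = R + household_count`.
#'
#' @param genome an `endo_genome`.
#' @return a list with `L`, `R`, `household_count`, and `type_counts`
#'   (named table of regulatory-gene counts per type).
#' @export
genome_stats <- function(genome) {
  hh <- sum(genome$kind == "H")
  gi <- genome$kind == "G"
  tc <- table(factor(genome$type_id[gi]))
  list(L = length(genome$kind), R = length(genome$kind) - hh,
       household_count = hh,
       type_counts = stats::setNames(as.integer(tc), names(tc)))
}

#' Regulatory region of a gene
#'
#' The regulatory region of a gene is the maximal contiguous run of binding
#' sites immediately upstream (lower positions) of the gene. The run is
#' terminated by any gene bead -- regulatory or household -- or by the genome
#' start, so relocating or deleting a single bead has only local effects.
#'
#' @param genome an `endo_genome`.
#' @param gene_index 1-based bead position of a regulatory gene.
#' @return integer vector of binding-site positions (possibly empty),
#'   in increasing order.
#' @export
regulatory_region <- function(genome, gene_index) {
  if (gene_index < 1L || gene_index > length(genome$kind) ||
      genome$kind[gene_index] != "G")
    stop("gene_index must address a regulatory gene", call. = FALSE)
  pos <- integer(0)
  i <- gene_index - 1L
  while (i >= 1L && genome$kind[i] == "B") {
    pos <- c(i, pos)
    i <- i - 1L
  }
  pos
}

# Flat lookup tables for the regulatory machinery of one genome; rebuilt
# whenever the bead list changes. site_gene maps each site (in site_pos
# order) to the index (into gene_pos order) of the gene whose region it
# belongs to, or 0.
build_regulatory_cache <- function(genome) {
  kind <- genome$kind
  gene_pos <- which(kind == "G")
  site_pos <- which(kind == "B")
  site_gene <- integer(length(site_pos))
  if (length(site_pos)) {
    owner <- integer(length(kind)) # per bead: owning gene index or 0
    current <- 0L
    for (i in rev(seq_along(kind))) {
      if (kind[i] == "G") current <- i
      else if (kind[i] == "B") owner[i] <- current
      else current <- 0L # household breaks the run
    }
    gm <- match(owner[site_pos], gene_pos)
    site_gene <- ifelse(is.na(gm), 0L, gm)
  }
  # field order is relied upon by the compiled holobiont step
  list(
    gene_pos = gene_pos,
    site_pos = site_pos,
    site_gene = as.integer(site_gene),
    site_seq = genome$seq[site_pos],
    gene_seq = genome$seq[gene_pos],
    gene_type = genome$type_id[gene_pos],
    gene_sp = genome$sp[gene_pos],
    gene_w = genome$weight[gene_pos],
    gene_thr = genome$threshold[gene_pos],
    B = genome_B(genome)
  )
}

# signal-peptide mask: which genes' products stay in a compartment of the
# given role ("10" = host bit, "01" = symbiont bit, "00" = stays native)
sp_native_mask <- function(cache, role) {
  own_bit <- if (role == "host") 2L else 1L
  cache$gene_sp == 0L | bitwAnd(cache$gene_sp, own_bit) > 0L
}

# ---------------------------------------------------------------------------
# Text serialization (genome format v1): one bead per line, tab-separated.
#   #endocycle-genome v1 B=<int>
#   H
#   B <bits>
#   G <type_id> <bits> <sp2bits> <weight> <threshold>

#' Read and write the genome text format
#'
#' One bead per line, tab-separated: `H` for a household bead, `B <bits>`
#' for a binding site, and `G <type_id> <bits> <sp> <weight> <threshold>`
#' for a regulatory gene. The header line is
#' `#endocycle-genome v1 B=<int>`; other lines starting with `#` are
#' comments. `serialize_genome()` renders the canonical form;
#' `parse_genome()` accepts any conforming document, so
#' `serialize_genome(parse_genome(x))` is the canonical re-rendering of `x`.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param genome an `endo_genome`.
#' @param file optional path; `read_genome()`/`write_genome()` are the
#'   file-based versions.
#' @return `parse_genome()` an `endo_genome`; `serialize_genome()` a
#'   character vector of lines.
#' @export
parse_genome <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  B <- 20L
  header <- grep("^#endocycle-genome", text)
  if (length(header)) {
    m <- regmatches(text[header[1]], regexec("B=([0-9]+)", text[header[1]]))[[1]]
    if (length(m) == 2L) B <- as.integer(m[2])
  }
  init_line <- grep("^#init-expression\\s", text)
  init_bits <- if (length(init_line)) {
    sub("^#init-expression\\s+", "", text[init_line[1]])
  } else NULL
  beads <- list()
  for (ln in seq_along(text)) {
    line <- trimws(text[ln])
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    bead <- switch(f[1],
      H = {
        if (length(f) != 1L) parse_fail(ln, "household line takes no fields")
        household_bead()
      },
      B = {
        if (length(f) != 2L) parse_fail(ln, "binding-site line needs 1 field")
        site_bead(parse_bits(f[2], B, ln))
      },
      G = {
        if (length(f) != 6L) parse_fail(ln, "gene line needs 5 fields")
        if (nchar(f[4]) != 2L || !grepl("^[01]{2}$", f[4]))
          parse_fail(ln, "signal peptide must be 2 bits")
        gene_bead(parse_int(f[2], ln), parse_bits(f[3], B, ln), f[4],
                  parse_int(f[5], ln), parse_int(f[6], ln))
      },
      parse_fail(ln, paste0("unknown bead kind '", f[1], "'"))
    )
    beads[[length(beads) + 1L]] <- bead
  }
  g <- new_genome(beads, B = B)
  if (!is.null(init_bits)) {
    ng <- sum(g$kind == "G")
    if (!grepl("^[01]+$", init_bits) || nchar(init_bits) != ng)
      parse_fail(init_line[1], "init-expression must have one bit per gene")
    attr(g, "init_expression") <-
      as.integer(strsplit(init_bits, "")[[1]]) == 1L
  }
  g
}

parse_fail <- function(line, msg) {
  stop(sprintf("genome parse error at line %d: %s", line, msg), call. = FALSE)
}

parse_bits <- function(s, B, ln) {
  if (!grepl("^[01]+$", s)) parse_fail(ln, "malformed bit vector")
  if (nchar(s) != B) parse_fail(ln, sprintf("bit vector has %d bits, expected B=%d", nchar(s), B))
  bits_to_mask(s)
}

parse_int <- function(s, ln) {
  v <- suppressWarnings(as.integer(s))
  if (is.na(v)) parse_fail(ln, paste0("not an integer: '", s, "'"))
  v
}

#' @rdname parse_genome
#' @export
serialize_genome <- function(genome) {
  B <- genome_B(genome)
  lines <- sprintf("#endocycle-genome v1 B=%d", B)
  init <- attr(genome, "init_expression")
  if (!is.null(init))
    lines <- c(lines, paste0("#init-expression ",
                             paste(as.integer(init), collapse = "")))
  for (i in seq_along(genome$kind)) {
    lines <- c(lines, switch(genome$kind[i],
      H = "H",
      B = paste("B", mask_to_string(genome$seq[i], B), sep = "\t"),
      G = paste("G", genome$type_id[i], mask_to_string(genome$seq[i], B),
                sp_to_string(genome$sp[i]), genome$weight[i],
                genome$threshold[i], sep = "\t")
    ))
  }
  lines
}

#' @rdname parse_genome
#' @export
read_genome <- function(file) parse_genome(readLines(file))

#' @rdname parse_genome
#' @export
write_genome <- function(genome, file) {
  writeLines(serialize_genome(genome), file)
  invisible(file)
}
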