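#' Cysteine architecture profile of a metallothionein sequence
#'
#' Reports Cys positions (1-based), non-overlapping left-to-right counts of
#' the classical CC, CXC and CXXC motifs, and a domain partition that groups
#' consecutive cysteines into blocks of nine — the classical snail-MT domain
#' carries nine cysteines — splitting at the largest inter-Cys gaps.
#'
#' @param sequence 1-letter protein sequence (gaps `-` are ignored for
#'   counting but positions refer to the ungapped sequence).
#' @return Object of class `cys_profile`: list with `n_residues`,
#'   `cys_positions`, `motif_counts`, `domain_partition` (data frame with
#'   `start`, `end`, `n_cys`; residue coordinates, 1-based inclusive).
#' @export
cys_profile <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- gsub("-", "", toupper(sequence))
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  pos <- which(aa == "C")

  motifs <- c(CC = 0L, CXC = 0L, CXXC = 0L)
  i <- 1L
  while (i <= n) {
    if (aa[i] == "C") {
      if (i + 1L <= n && aa[i + 1L] == "C") {
        motifs[["CC"]] <- motifs[["CC"]] + 1L; i <- i + 2L; next
      }
      if (i + 2L <= n && aa[i + 2L] == "C" && aa[i + 1L] != "C") {
        motifs[["CXC"]] <- motifs[["CXC"]] + 1L; i <- i + 3L; next
      }
      if (i + 3L <= n && aa[i + 3L] == "C" &&
          aa[i + 1L] != "C" && aa[i + 2L] != "C") {
        motifs[["CXXC"]] <- motifs[["CXXC"]] + 1L; i <- i + 4L; next
      }
    }
    i <- i + 1L
  }

  partition <- .partition_cys_domains(pos, n)
  structure(list(n_residues = n, cys_positions = pos, motif_counts = motifs,
                 domain_partition = partition),
            class = "cys_profile")
}

# Group k cysteines into ceiling(k/9) blocks by cutting at the largest
# inter-Cys gaps; blocks are reported in sequence order and sized as evenly
# as the gap structure allows, preferring full 9-Cys blocks from the left.
.partition_cys_domains <- function(pos, n_residues) {
  k <- length(pos)
  if (k == 0) {
    return(data.frame(start = integer(0), end = integer(0), n_cys = integer(0)))
  }
  n_dom <- ceiling(k / 9)
  if (n_dom == 1) {
    return(data.frame(start = pos[1], end = pos[k], n_cys = k))
  }
  gaps <- diff(pos)                    # k-1 inter-Cys gaps
  cut_after <- sort(order(gaps, decreasing = TRUE)[seq_len(n_dom - 1)])
  bounds <- c(0, cut_after, k)
  do.call(rbind, lapply(seq_len(n_dom), function(d) {
    idx <- (bounds[d] + 1):bounds[d + 1]
    data.frame(start = pos[idx[1]], end = pos[idx[length(idx)]],
               n_cys = length(idx))
  }))
}

#' @export
print.cys_profile <- function(x, ...) {
  cat(sprintf("%d residues, %d Cys\n", x$n_residues, length(x$cys_positions)))
  cat("  motifs:", paste(sprintf("%s=%d", names(x$motif_counts),
                                 x$motif_counts), collapse = ", "), "\n")
  if (nrow(x$domain_partition)) {
    cat("  domains (start-end: nCys):",
        paste(sprintf("%d-%d:%d", x$domain_partition$start,
                      x$domain_partition$end, x$domain_partition$n_cys),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Predicted divalent-metal capacity from the cysteine count
#'
#' The classical snail-MT stoichiometry binds three divalent ions per nine
#' cysteines (a 9:3 Cys:metal ratio), i.e. one ion per three cysteines:
#' `floor(n_cys / 3)`.
#'
#' @param n_cys Non-negative cysteine count.
#' @return Predicted number of Zn2+/Cd2+ ions.
#' @examples
#' predicted_divalent_capacity(33)  # 11
#' @export
predicted_divalent_capacity <- function(n_cys) {
  stopifnot(all(n_cys >= 0))
  floor(n_cys / 3)
}

#' Predicted Cu(I) capacity range from the cysteine count
#'
#' A nine-cysteine domain accommodates four to six Cu+ ions; the range scales
#' linearly with the cysteine count: `(floor(n_cys/9*4), floor(n_cys/9*6))`.
#'
#' @param n_cys Non-negative cysteine count.
#' @return Integer vector `c(min, max)`.
#' @examples
#' predicted_cu_capacity(9)   # c(4, 6)
#' @export
predicted_cu_capacity <- function(n_cys) {
  stopifnot(all(n_cys >= 0), length(n_cys) == 1L)
  c(min = floor(n_cys / 9 * 4), max = floor(n_cys / 9 * 6))
}

#' Label structural deviations of an aligned query vs a reference
#'
#' Consumes a user-supplied pairwise alignment (equal-length gapped
#' sequences) and labels: internal query gap runs of >= `min_deletion`
#' columns as Deletion, terminal query gap runs as Truncation, and terminal
#' reference gap runs as Extension (extra query sequence beyond the
#' reference). Also counts columns where both sequences carry a cysteine.
#'
#' @param aligned_query,aligned_reference Gapped sequences of equal length
#'   (`-` for gaps).
#' @param min_deletion Minimum internal gap run to call a Deletion (default 3).
#' @return List of class `deviation_report` with `labels` (data frame:
#'   `type`, `start`, `end`, `length` in alignment columns) and
#'   `conserved_cys` count.
#' @export
deviation_report <- function(aligned_query, aligned_reference,
                             min_deletion = 3L) {
  q <- strsplit(toupper(aligned_query), "")[[1]]
  r <- strsplit(toupper(aligned_reference), "")[[1]]
  if (length(q) != length(r)) stop("aligned sequences must have equal length")
  n <- length(q)

  runs_of <- function(is_gap) {
    rle_ <- rle(is_gap)
    ends <- cumsum(rle_$lengths)
    starts <- ends - rle_$lengths + 1L
    data.frame(start = starts, end = ends, gap = rle_$values)
  }

  labels <- data.frame(type = character(0), start = integer(0),
                       end = integer(0), length = integer(0))
  add <- function(type, s, e) {
    rbind(labels, data.frame(type = type, start = s, end = e,
                             length = e - s + 1L))
  }

  qr <- runs_of(q == "-")
  for (i in seq_len(nrow(qr))) {
    if (!qr$gap[i]) next
    s <- qr$start[i]; e <- qr$end[i]
    if (s == 1L || e == n) {
      labels <- add("Truncation", s, e)
    } else if (e - s + 1L >= min_deletion) {
      labels <- add("Deletion", s, e)
    }
  }
  rr <- runs_of(r == "-")
  for (i in seq_len(nrow(rr))) {
    if (!rr$gap[i]) next
    s <- rr$start[i]; e <- rr$end[i]
    if (s == 1L || e == n) labels <- add("Extension", s, e)
  }

  structure(list(labels = labels, conserved_cys = sum(q == "C" & r == "C")),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  if (nrow(x$labels)) print(x$labels, row.names = FALSE)
  else cat("no structural deviations\n")
  cat("conserved Cys columns:", x$conserved_cys, "\n")
  invisible(x)
}
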