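## Evidence-based scaffolding. Cross-scaffold mate pairs vote for joins
## between scaffold ends; an ambiguity guard keeps an end's best join only
## when it clearly dominates, the resulting end graph is a union of simple
## paths (cycles broken at their weakest edge), and paths are emitted as
## FASTA + AGP with gap sizes estimated from the library insert.

## which scaffold end a read implies, and how far its outer coordinate is
## from that end. Outward geometry: a '-' read expects its mate to the
## right (tail end); a '+' read to the left (head end). Inward: reversed.
implied_end <- function(strand, start, end, scaf_len, geometry = "outward") {
  to_tail <- if (geometry == "outward") strand == "-" else strand == "+"
  list(end = fifelse(to_tail, "tail", "head"),
       dist = fifelse(to_tail, scaf_len - start, end))
}

#' Collect join candidates from cross-scaffold mate pairs
#'
#' Each cross-scaffold pair implies a join between two scaffold ends: the
#' end each read points its mate towards. Reads farther than `lib$upper`
#' from the end they imply are ignored (the mate could not reach another
#' scaffold from there). Candidates with at least `min_support` pairs are
#' kept; the gap between the two ends is estimated as the median over
#' supporting pairs of `mu - d_a - d_b`, where `d` is the distance from a
#' read's outer coordinate to its implied end.
#'
#' @param pairs A cleaned pair table (scaffolding profile).
#' @param lengths Named numeric vector of scaffold lengths.
#' @param lib A [library_model()].
#' @param min_support Minimum supporting pairs per candidate (default 5).
#' @param geometry Library read geometry (`"outward"` or `"inward"`).
#' @return A `data.table` of join candidates: `a_id`, `a_end`, `b_id`,
#'   `b_end`, `relative_orientation` (`same`/`flipped`), `support`,
#'   `gap_estimate`.
#' @export
collect_links <- function(pairs, lengths, lib = library_model(), min_support = 5L,
                          geometry = c("outward", "inward")) {
  geometry <- match.arg(geometry)
  empty <- data.table(a_id = character(), a_end = character(), b_id = character(),
                      b_end = character(), relative_orientation = character(),
                      support = integer(), gap_estimate = numeric())
  x <- pairs[!(same_scaffold)]
  if (!nrow(x)) return(empty)
  e1 <- implied_end(x$strand1, x$start1, x$end1, lengths[x$scaffold1], geometry)
  e2 <- implied_end(x$strand2, x$start2, x$end2, lengths[x$scaffold2], geometry)
  ok <- e1$dist <= lib$upper & e2$dist <= lib$upper
  if (!any(ok)) return(empty)
  x <- data.table(a_id = x$scaffold1[ok], a_end = e1$end[ok], d_a = e1$dist[ok],
                  b_id = x$scaffold2[ok], b_end = e2$end[ok], d_b = e2$dist[ok])
  ## pairs are already in canonical scaffold order (a_id < b_id)
  x[, gap := lib$mu - d_a - d_b]
  cand <- x[, .(support = .N, gap_estimate = median(gap)),
            by = .(a_id, a_end, b_id, b_end)]
  cand <- cand[support >= min_support]
  cand[, relative_orientation := fifelse(a_end != b_end, "same", "flipped")]
  setorder(cand, a_id, a_end, b_id, b_end)
  cand[, .(a_id, a_end, b_id, b_end, relative_orientation, support, gap_estimate)]
}

#' Resolve join candidates into a conflict-free end graph
#'
#' Each scaffold end may carry at most one join. When an end has several
#' candidates, the strongest is kept only if its support is at least
#' `dominance` times the runner-up's; otherwise ALL candidates at that end
#' are discarded (ambiguity guard -- precision over recall, reflecting
#' that a wrong join is far more damaging than a missed one). Self-joins
#' are dropped, and any remaining cycle is broken at its lowest-support
#' edge, so the result is a union of simple paths.
#'
#' @param candidates Output of [collect_links()].
#' @param dominance Required support ratio between best and runner-up
#'   (default 2).
#' @return The surviving candidate edges.
#' @export
build_join_graph <- function(candidates, dominance = 2) {
  cand <- as.data.table(candidates)
  cand <- cand[a_id != b_id]
  if (!nrow(cand)) return(cand)
  cand[, edge_id := .I]
  ends <- rbind(cand[, .(node = paste0(a_id, ":", a_end), support, edge_id)],
                cand[, .(node = paste0(b_id, ":", b_end), support, edge_id)])
  winner <- ends[order(node, -support, edge_id)][, {
    if (.N == 1L || support[1] >= dominance * support[2])
      .(edge_id = edge_id[1]) else .(edge_id = NA_integer_)
  }, by = node]
  ## an edge survives iff it is the (unambiguous) winner at both ends
  win_at <- function(node_name) winner$edge_id[match(node_name, winner$node)]
  surv <- cand[win_at(paste0(a_id, ":", a_end)) == edge_id &
                 win_at(paste0(b_id, ":", b_end)) == edge_id]
  if (!nrow(surv)) return(surv[, !"edge_id"])
  ## break cycles: components where every scaffold has both ends joined
  surv <- break_cycles(surv)
  surv[, !"edge_id"][]
}

## remove the lowest-support edge of every cycle in a degree-<=1-per-end graph
break_cycles <- function(edges) {
  repeat {
    adj <- rbind(edges[, .(id = a_id, edge_id, support)],
                 edges[, .(id = b_id, edge_id, support)])
    ## walk components
    drop <- integer(0)
    seen <- character(0)
    for (start_id in sort(unique(adj$id))) {
      if (start_id %in% seen) next
      ## collect component by flood fill over edges
      comp <- start_id
      repeat {
        e <- edges[a_id %in% comp | b_id %in% comp]
        ids <- union(e$a_id, e$b_id)
        if (all(ids %in% comp)) break
        comp <- union(comp, ids)
      }
      seen <- c(seen, comp)
      e <- edges[a_id %in% comp & b_id %in% comp]
      if (nrow(e) >= length(comp)) {
        ## edges >= nodes in a degree-constrained component => a cycle
        drop <- c(drop, e$edge_id[which.min(e$support)])
      }
    }
    if (!length(drop)) return(edges)
    edges <- edges[!edge_id %in% drop]
  }
}

#' Linearize the join graph into scaffold paths
#'
#' Walks each component of the resolved end graph from a free end,
#' propagating orientation (entering a contig through its head gives '+',
#' through its tail '-'). Each path is reported in the direction that puts
#' its lexicographically smallest contig id on the '+' strand, so output is
#' deterministic and invariant to input permutation. Contigs without joins
#' become singleton paths. Gap estimates are clamped below at `min_gap`.
#'
#' @param edges Resolved edges from [build_join_graph()].
#' @param contig_ids All contig ids (joined or not).
#' @param min_gap Minimum rendered gap in bp (default 20).
#' @return A scaffold-path table: `object`, `contig`, `orient`,
#'   `gap_after` (`NA` on the last component of each object).
#' @export
linearize <- function(edges, contig_ids, min_gap = 20) {
  edges <- as.data.table(edges)
  key <- function(id, end) paste0(id, ":", end)
  emap <- new.env(parent = emptyenv())
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      assign(key(edges$a_id[i], edges$a_end[i]), i, envir = emap)
      assign(key(edges$b_id[i], edges$b_end[i]), i, envir = emap)
    }
    deg_chk <- c(paste0(edges$a_id, ":", edges$a_end), paste0(edges$b_id, ":", edges$b_end))
    if (anyDuplicated(deg_chk))
      stop("an end carries more than one join; run build_join_graph() first")
  }
  edge_at <- function(id, end) {
    k <- key(id, end)
    if (exists(k, envir = emap, inherits = FALSE)) get(k, envir = emap) else NA_integer_
  }
  unvisited <- sort(unique(contig_ids))
  paths <- list()
  while (length(unvisited)) {
    ## find a contig with at least one free end to start from
    start <- NULL
    for (id in unvisited) {
      free_head <- is.na(edge_at(id, "head"))
      free_tail <- is.na(edge_at(id, "tail"))
      if (free_head || free_tail) {
        ## enter through the free end: entering via head => '+'
        start <- list(id = id, enter = if (free_head) "head" else "tail")
        break
      }
    }
    if (is.null(start))
      stop("residual cycle in join graph; run build_join_graph() first")
    chain <- character(0); orient <- character(0); gaps <- numeric(0)
    cur <- start$id; enter <- start$enter
    repeat {
      chain <- c(chain, cur)
      orient <- c(orient, if (enter == "head") "+" else "-")
      unvisited <- setdiff(unvisited, cur)
      exit <- if (enter == "head") "tail" else "head"
      ei <- edge_at(cur, exit)
      if (is.na(ei)) break
      e <- edges[ei]
      if (e$a_id == cur && e$a_end == exit) {
        nxt <- e$b_id; enter <- e$b_end
      } else {
        nxt <- e$a_id; enter <- e$a_end
      }
      if (nxt %in% chain) stop("cycle encountered during linearization")
      gaps <- c(gaps, round(max(e$gap_estimate, min_gap)))
      cur <- nxt
    }
    ## canonical direction: smallest contig id on '+'
    anchor <- which(chain == min(chain))[1]
    if (orient[anchor] == "-") {
      chain <- rev(chain)
      orient <- rev(ifelse(orient == "+", "-", "+"))
      gaps <- rev(gaps)
    }
    paths <- c(paths, list(data.table(
      contig = chain, orient = orient,
      gap_after = c(gaps, NA_real_)[seq_along(chain)]
    )))
  }
  ## deterministic path order and naming
  first_id <- vapply(paths, function(p) p$contig[1], character(1))
  paths <- paths[order(first_id)]
  out <- rbindlist(lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    obj <- if (nrow(p) == 1L) p$contig else sprintf("ml_scaffold_%04d", i)
    cbind(data.table(object = obj), p)
  }))
  out[]
}

#' Emit scaffold sequences (and AGP rows) from paths
#'
#' Renders each path as one sequence: components in order, '-' components
#' reverse-complemented, gaps as runs of `N` of length
#' `max(gap_estimate, min_gap)`.
#'
#' @param paths A scaffold-path table ([linearize()]).
#' @param sequences Named character vector of contig sequences.
#' @param min_gap Minimum rendered gap (default 20); applied again
#'   defensively if `paths` carries smaller gaps.
#' @return A list: `records` (named character vector of scaffold
#'   sequences) and `paths` (the path table with clamped gaps).
#' @export
emit_scaffolds <- function(paths, sequences, min_gap = 20) {
  p <- copy(as.data.table(paths))
  missing <- setdiff(p$contig, names(sequences))
  if (length(missing)) stop("missing contig sequence: ", paste(missing, collapse = ", "))
  p[!is.na(gap_after), gap_after := round(pmax(gap_after, min_gap))]
  recs <- agp_to_fasta(p, sequences)
  list(records = recs, paths = p[])
}

#' Assembly contiguity statistics
#'
#' N50 (N10) is the length of the sequence at which the cumulative length,
#' taken in descending order, first reaches 50% (10%) of the assembly
#' total.
#'
#' @param lengths Numeric vector of sequence lengths (or a named character
#'   vector of sequences).
#' @return A one-row `data.table`: `n_sequences`, `total_bp`, `largest`,
#'   `n50`, `n10`.
#' @export
assembly_stats <- function(lengths) {
  if (is.character(lengths)) lengths <- nchar(lengths)
  if (!length(lengths)) stop("no sequences")
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(l)
  nX <- function(frac) l[which(cum >= frac * sum(l))[1]]
  data.table(n_sequences = length(l), total_bp = sum(l), largest = l[1],
             n50 = nX(0.5), n10 = nX(0.1))
}

#' Scaffold an assembly with mate-pair links
#'
#' End-to-end scaffolding: collect cross-scaffold links, resolve the join
#' graph, linearize, and emit sequences with contiguity statistics before
#' and after.
#'
#' @param pairs A cleaned pair table (scaffolding profile).
#' @param sequences Named character vector of input contig/scaffold
#'   sequences.
#' @param lib A [library_model()].
#' @param min_support Minimum supporting pairs per join (default 5).
#' @param min_gap Minimum rendered gap (default 20).
#' @param dominance Ambiguity-guard ratio (default 2).
#' @param geometry Library read geometry.
#' @return A list: `candidates`, `edges`, `paths`, `records`,
#'   `stats_before`, `stats_after`.
#' @export
scaffold_assembly <- function(pairs, sequences, lib = library_model(),
                              min_support = 5L, min_gap = 20, dominance = 2,
                              geometry = c("outward", "inward")) {
  geometry <- match.arg(geometry)
  lengths <- setNames(nchar(sequences), names(sequences))
  cand <- collect_links(pairs, lengths, lib, min_support = min_support,
                        geometry = geometry)
  edges <- build_join_graph(cand, dominance = dominance)
  paths <- linearize(edges, names(sequences), min_gap = min_gap)
  out <- emit_scaffolds(paths, sequences, min_gap = min_gap)
  list(candidates = cand, edges = edges, paths = out$paths, records = out$records,
       stats_before = assembly_stats(lengths),
       stats_after = assembly_stats(out$records))
}
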