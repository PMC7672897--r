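# Graph cleaning: spectral (low-frequency edge trimming) and structural
# (tips, bubbles, chimeric connections) error removal. All operations are
# monotone - node and link counts never increase - and deterministic:
# candidates are processed in (frequency, sequence) order.

#' Trim low-frequency links
#'
#' Removes every link with read support strictly below `cs`, then removes
#' nodes left with no links whose coverage is also below `cs`. `cs = 0`
#' leaves the graph unchanged.
#'
#' @param g An `assembly_graph`.
#' @param cs Frequency cutoff (>= 0).
#' @return The trimmed graph.
#' @export
trim_edges <- function(g, cs) {
  cs <- as.integer(cs)
  if (cs < 0L) stop("cs must be >= 0")
  if (cs == 0L) return(g)
  links <- g$links[freq >= cs]
  linked <- unique(c(links$a, links$b))
  nodes <- g$nodes[id %in% linked | cov >= cs]
  renumber_graph(new_graph(g$k, nodes, links))
}

# drop a set of node ids (and their links), keep everything else
drop_nodes <- function(g, ids) {
  nodes <- g$nodes[!id %in% ids]
  links <- g$links[!(a %in% ids | b %in% ids)]
  renumber_graph(new_graph(g$k, nodes, links))
}

#' Prune short dead-end tips
#'
#' A tip is a node with exactly one link whose sequence is at most
#' `max_tip_len` bp; it is removed when the junction it hangs off offers an
#' alternative link of frequency at least its own. Tips are removed one at
#' a time, lowest frequency first (ties by sequence), with re-compaction,
#' until a fixpoint.
#'
#' @param g An `assembly_graph`.
#' @param max_tip_len Maximum tip length in bp (default 2k).
#' @return The pruned graph.
#' @export
prune_tips <- function(g, max_tip_len = 2L * g$k) {
  repeat {
    g <- compact_graph(g)
    links <- g$links
    if (nrow(links) == 0L) return(g)
    sc <- side_counts(links)
    per_node <- sc[, .(total = sum(nlinks)), by = node]
    tip_ids <- per_node[total == 1L, node]
    tip_ids <- tip_ids[g$nodes$len[tip_ids] <= max_tip_len]
    if (!length(tip_ids)) return(g)
    ep <- link_endpoints(links)
    cand <- NULL
    for (t in tip_ids) {
      lrow0 <- ep[node == t, lrow][1L]
      l <- links[lrow0]
      # the junction endpoint is the other end of the tip's sole link
      if (l$a == t) { jn <- l$b; js <- to_side(l$ob) }
      else { jn <- l$a; js <- from_side(l$oa) }
      if (jn == t) next  # self-link, not a competing junction
      others <- ep[node == jn & side == js & lrow != lrow0, lrow]
      if (length(others) && max(links$freq[others]) >= l$freq) {
        cand <- rbind(cand, data.table(tip = t, freq = l$freq,
                                       seq = g$nodes$seq[t]))
      }
    }
    if (is.null(cand) || nrow(cand) == 0L) return(g)
    setorder(cand, freq, seq)
    g <- drop_nodes(g, cand$tip[1L])
  }
}

# percent identity of two equal-ish length sequences via global alignment
align_identity <- function(s1, s2) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(s1),
                                      Biostrings::DNAString(s2),
                                      type = "global")
  Biostrings::pid(pa) / 100
}

# simple-bubble branches: nodes with exactly one link per side; returns
# a table of branch nodes with their two junction attachments
bubble_branches <- function(g) {
  links <- g$links
  sc <- side_counts(links)
  both <- dcast(sc, node ~ side, value.var = "nlinks", fill = 0L)
  if (!"L" %in% names(both)) both[, L := 0L]
  if (!"R" %in% names(both)) both[, R := 0L]
  cand_nodes <- both[L == 1L & R == 1L, node]
  if (!length(cand_nodes)) return(NULL)
  ep <- link_endpoints(links)
  out <- list()
  for (n in cand_nodes) {
    rows <- ep[node == n]
    if (nrow(rows) != 2L || length(unique(rows$side)) != 2L) next
    att <- lapply(rows$lrow, function(lr) {
      l <- links[lr]
      if (l$a == n) list(node = l$b, side = to_side(l$ob), lrow = lr,
                         freq = l$freq)
      else list(node = l$a, side = from_side(l$oa), lrow = lr, freq = l$freq)
    })
    # my L-side attachment first for a canonical description
    ls <- rows$side == "L"
    attL <- att[[which(ls)]]; attR <- att[[which(!ls)]]
    if (attL$node == n || attR$node == n) next
    e1 <- paste0(attL$node, attL$side); e2 <- paste0(attR$node, attR$side)
    flipped <- e2 < e1
    bkey <- if (flipped) paste(e2, e1) else paste(e1, e2)
    out[[length(out) + 1L]] <- data.table(
      node = n, bkey = bkey, flipped = flipped,
      freq = attL$freq + attR$freq,
      lrow1 = attL$lrow, lrow2 = attR$lrow)
  }
  if (!length(out)) return(NULL)
  rbindlist(out)
}

#' Pop simple bubbles
#'
#' Where two single-link-per-side branch nodes of length at most
#' `max_bubble_len` connect the same pair of junction sides and their
#' sequences align at identity >= `min_identity`, the lower-frequency
#' branch is deleted and its link frequencies are added to the survivor's.
#' Iterates, with re-compaction, to a fixpoint.
#'
#' @param g An `assembly_graph`.
#' @param max_bubble_len Maximum branch length in bp (default 3k).
#' @param min_identity Minimum alignment identity between the branches.
#' @return The graph with bubbles collapsed.
#' @export
pop_bubbles <- function(g, max_bubble_len = 3L * g$k, min_identity = 0.9) {
  repeat {
    g <- compact_graph(g)
    br <- bubble_branches(g)
    if (is.null(br)) return(g)
    br <- br[g$nodes$len[node] <= max_bubble_len]
    dup <- br[, .N, by = bkey][N >= 2L, bkey]
    if (!length(dup)) return(g)
    popped <- FALSE
    for (kk in sort(dup)) {
      grp <- br[bkey == kk]
      grp[, seq_ := g$nodes$seq[node]]
      setorder(grp, -freq, seq_)
      keep <- grp[1L]
      for (i in 2L:nrow(grp)) {
        lose <- grp[i]
        s_keep <- g$nodes$seq[keep$node]
        s_lose <- g$nodes$seq[lose$node]
        if (keep$flipped != lose$flipped) s_lose <- reverse_complement(s_lose)
        if (align_identity(s_keep, s_lose) < min_identity) next
        # transfer support onto the survivor's links, matching by junction
        lk <- if (keep$flipped == lose$flipped) c(keep$lrow1, keep$lrow2)
              else c(keep$lrow2, keep$lrow1)
        g$links[lk[1L], freq := freq + g$links$freq[lose$lrow1]]
        g$links[lk[2L], freq := freq + g$links$freq[lose$lrow2]]
        g$nodes[keep$node, cov := cov + g$nodes$cov[lose$node]]
        g <- drop_nodes(g, lose$node)
        popped <- TRUE
        break
      }
      if (popped) break  # indices stale after a removal; restart scan
    }
    if (!popped) return(g)
  }
}

#' Remove chimeric connections
#'
#' Deletes internal links - links both of whose attachment sides carry at
#' least one other link - whose frequency is below `cs` and below half the
#' median frequency of the other links at the two attachment sides.
#' Re-compacts afterwards.
#'
#' @param g An `assembly_graph`.
#' @param cs Frequency cutoff.
#' @return The cleaned graph.
#' @export
remove_chimeric_links <- function(g, cs) {
  links <- g$links
  if (nrow(links) == 0L) return(g)
  sc <- side_counts(links)
  n_a <- count_at(sc, links$a, from_side(links$oa))
  n_b <- count_at(sc, links$b, to_side(links$ob))
  internal <- which(n_a >= 2L & n_b >= 2L & links$freq < cs)
  if (!length(internal)) return(compact_graph(g))
  ep <- link_endpoints(links)
  bad <- logical(nrow(links))
  for (i in internal) {
    l <- links[i]
    nb <- ep[(node == l$a & side == from_side(l$oa)) |
             (node == l$b & side == to_side(l$ob)), lrow]
    nb <- setdiff(nb, i)
    if (length(nb) && l$freq < stats::median(links$freq[nb]) / 2) {
      bad[i] <- TRUE
    }
  }
  if (!any(bad)) return(compact_graph(g))
  compact_graph(new_graph(g$k, g$nodes, links[!bad]))
}

#' Clean an assembly graph
#'
#' Runs the full cleaning cascade: low-frequency link trimming, unitig
#' compaction, tip pruning, bubble popping and chimeric-link removal.
#'
#' @param g An `assembly_graph`.
#' @param cs Frequency cutoff for spectral cleaning.
#' @param max_tip_len,max_bubble_len,min_bubble_identity Structural
#'   cleaning parameters (defaults 2k, 3k, 0.9).
#' @return The cleaned, compacted graph.
#' @export
clean_graph <- function(g, cs = 5L, max_tip_len = 2L * g$k,
                        max_bubble_len = 3L * g$k,
                        min_bubble_identity = 0.9) {
  g <- trim_edges(g, cs)
  g <- compact_graph(g)
  g <- prune_tips(g, max_tip_len)
  g <- pop_bubbles(g, max_bubble_len, min_bubble_identity)
  g <- remove_chimeric_links(g, cs)
  g
}
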