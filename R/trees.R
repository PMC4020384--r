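#' Time-calibrated phylogeny container
#'
#' Simulation works on rooted trees whose nodes carry *heights*: time
#' before the most recently sampled tip (height 0 = youngest tip, larger
#' = older).  A `timetree` wraps an [ape] `phylo` object together with a
#' height for every node (indexed by ape node number) and a flag saying
#' whether branch lengths are calibrated in time units or are plain
#' substitution units (in which case the default clock rate of 1 makes
#' them interchangeable).
#'
#' @param phy A rooted `phylo` object with branch lengths.
#' @param heights Numeric vector of node heights indexed by ape node
#'   number (tips `1..n`, internals `n+1..n+Nnode`).
#' @param time_units Logical; `TRUE` when heights are calendar time.
#' @return An object of class `"timetree"`.
#' @export
timetree <- function(phy, heights, time_units = FALSE) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object")
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  if (length(heights) != n_nodes) {
    stop("need one height per node (", n_nodes, ")")
  }
  if (any(!is.finite(heights)) || any(heights < -1e-9)) {
    stop("heights must be finite and >= 0")
  }
  heights[heights < 0] <- 0
  ## parent - child height difference must equal the branch length
  dh <- heights[phy$edge[, 1]] - heights[phy$edge[, 2]]
  if (any(abs(dh - phy$edge.length) > 1e-6)) {
    stop("node heights inconsistent with branch lengths")
  }
  structure(list(phy = phy, heights = heights,
                 time_units = isTRUE(time_units)),
            class = "timetree")
}

#' @export
print.timetree <- function(x, ...) {
  cat("timetree:", ape::Ntip(x$phy), "tips, root height",
      format(root_height(x), digits = 6),
      if (x$time_units) "(time units)" else "(substitution units)", "\n")
  invisible(x)
}

#' @rdname timetree
#' @param tree A `timetree`.
#' @export
root_height <- function(tree) {
  stopifnot(inherits(tree, "timetree"))
  root <- ape::Ntip(tree$phy) + 1L
  tree$heights[root]
}

#' @rdname timetree
#' @export
tip_heights <- function(tree) {
  stopifnot(inherits(tree, "timetree"))
  h <- tree$heights[seq_len(ape::Ntip(tree$phy))]
  names(h) <- tree$phy$tip.label
  h
}

#' Read a set of taxa with sampling heights
#'
#' Parses tab-delimited rows `name<TAB>height`.  Heights are times before
#' the most recent sample; setting all heights to 0 describes
#' contemporaneously sampled taxa.
#'
#' @param x Path to a file, or the text itself (anything containing a
#'   newline or tab is treated as text).
#' @param header Skip one header line when `TRUE`.
#' @return A `taxon_set`: a data frame with columns `name` and `height`,
#'   in input order.
#' @examples
#' read_taxa_table("A\t0\nB\t12.5")
#' @export
read_taxa_table <- function(x, header = FALSE) {
  lines <- if (length(x) == 1 && !grepl("[\n\t]", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  if (header && length(lines)) lines <- lines[-1]
  lines_idx <- which(nzchar(trimws(lines)))
  nm <- character(0); ht <- numeric(0)
  for (i in lines_idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2) {
      stop("line ", i + header, ": expected 2 tab-separated fields, found ",
           length(fields))
    }
    h <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(h)) stop("line ", i + header, ": height '", fields[2],
                       "' is not a number")
    if (h < 0) stop("line ", i + header, ": negative height")
    nm <- c(nm, trimws(fields[1])); ht <- c(ht, h)
  }
  taxon_set(nm, ht)
}

#' @rdname read_taxa_table
#' @param name,height Vectors of taxon labels and sampling heights.
#' @export
taxon_set <- function(name, height = rep(0, length(name))) {
  name <- as.character(name)
  if (!length(name)) stop("empty taxon set")
  if (any(!nzchar(name))) stop("taxon names must be non-empty")
  if (anyDuplicated(name)) {
    stop("duplicate taxon name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (any(!is.finite(height)) || any(height < 0)) {
    stop("heights must be finite and >= 0")
  }
  structure(data.frame(name = name, height = as.numeric(height),
                       stringsAsFactors = FALSE),
            class = c("taxon_set", "data.frame"))
}

#' Parse a rooted tree from NEWICK or NEXUS
#'
#' Reads a tree (branch lengths mandatory) and assigns node heights.
#' Without tip height information, heights are set so the most recent tip
#' sits at height 0.  Supplying `tip_heights` both calibrates the tree in
#' time units and cross-checks the branch lengths: a discrepancy larger
#' than `1e-6` between supplied heights and the root-to-tip path lengths
#' is an error, not silently rescaled.
#'
#' Multifurcating trees are accepted (the simulation recursion does not
#' require binary nodes).  Internal node labels are kept but ignored.
#'
#' @param x NEWICK text, NEXUS text (starting with `#NEXUS`), or a path
#'   to a file containing either.
#' @param tip_heights Optional named numeric vector (or `taxon_set`)
#'   giving the sampling height of every tip.
#' @param time_units Mark the tree as time-calibrated even without
#'   `tip_heights` (e.g. an ultrametric dated tree).
#' @return A [timetree].
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' root_height(tr)  # 2
#' @export
parse_tree <- function(x, tip_heights = NULL, time_units = !is.null(tip_heights)) {
  txt <- if (length(x) == 1 && !grepl("[\n;(]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  is_nexus <- grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)
  if (!is_nexus) .check_newick_syntax(txt)
  phy <- if (is_nexus) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(txt, tf)
    out <- tryCatch(ape::read.nexus(tf), error = function(e) {
      stop("NEXUS parse error: ", conditionMessage(e))
    })
    if (inherits(out, "multiPhylo")) out[[1]] else out
  } else {
    tryCatch(ape::read.tree(text = txt), error = function(e) {
      stop("NEWICK parse error: ", conditionMessage(e))
    })
  }
  if (is.null(phy)) stop("tree parse error: no tree found in input")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("missing branch length(s): every branch must have an explicit length")
  }
  if (any(phy$edge.length < 0)) stop("negative branch length(s)")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  if (inherits(tip_heights, "taxon_set")) {
    tip_heights <- stats::setNames(tip_heights$height, tip_heights$name)
  }
  compute_heights(timetree_skeleton(phy, time_units), tip_heights)
}

## minimal structural NEWICK check with character positions, ahead of ape
.check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("NEWICK parse error: unmatched ')' at character ", i)
      }
    }
  }
  if (depth > 0L) {
    stop("NEWICK parse error: ", depth, " unclosed '(' by character ",
         length(chars))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("NEWICK parse error: missing terminating ';' at character ",
         length(chars))
  }
  invisible(TRUE)
}

## timetree with placeholder heights, to be filled by compute_heights()
timetree_skeleton <- function(phy, time_units = FALSE) {
  structure(list(phy = phy, heights = NULL, time_units = isTRUE(time_units)),
            class = "timetree")
}

#' Compute node heights from branch lengths
#'
#' Assigns node heights so that the parent-child height difference equals
#' each branch length and the minimum tip height is 0, or matches
#' `tip_heights` when supplied.  Idempotent; errors if supplied tip
#' heights contradict the branch lengths by more than `1e-6`.
#'
#' @param tree A [timetree] (heights may be missing or stale).
#' @param tip_heights Optional named vector of tip sampling heights.
#' @return The tree with consistent heights.
#' @export
compute_heights <- function(tree, tip_heights = NULL) {
  stopifnot(inherits(tree, "timetree"))
  phy <- tree$phy
  n_tip <- ape::Ntip(phy)
  n_nodes <- n_tip + phy$Nnode
  root <- n_tip + 1L
  ## depth below root via preorder sweep
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  el <- ape::reorder.phylo(phy, "postorder")$edge.length
  depth <- rep(NA_real_, n_nodes)
  depth[root] <- 0
  for (k in rev(seq_len(nrow(edge)))) {   # postorder reversed = preorder
    depth[edge[k, 2]] <- depth[edge[k, 1]] + el[k]
  }
  tip_depth <- depth[seq_len(n_tip)]
  if (is.null(tip_heights)) {
    H <- max(tip_depth)
  } else {
    if (inherits(tip_heights, "taxon_set")) {
      tip_heights <- stats::setNames(tip_heights$height, tip_heights$name)
    }
    miss <- setdiff(phy$tip.label, names(tip_heights))
    if (length(miss)) {
      stop("tip_heights missing for: ", paste(miss, collapse = ", "))
    }
    want <- as.numeric(tip_heights[phy$tip.label])
    if (any(want < 0)) stop("tip heights must be >= 0")
    Hs <- want + tip_depth
    if (diff(range(Hs)) > 1e-6) {
      stop("supplied tip heights are inconsistent with branch lengths ",
           "(max discrepancy ", format(diff(range(Hs))), ")")
    }
    H <- mean(Hs)
  }
  heights <- H - depth
  heights[abs(heights) < 1e-12] <- 0
  timetree(phy, heights, tree$time_units)
}

#' Write a tree as NEWICK
#'
#' Branch lengths are written at full precision so that
#' `parse_tree(write_newick(t))` reproduces topology, branch lengths (to
#' 1e-9) and tip heights.
#'
#' @param tree A [timetree] or `phylo`.
#' @param file Optional path; when `NULL` the NEWICK string is returned.
#' @return NEWICK string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  phy <- if (inherits(tree, "timetree")) tree$phy else tree
  txt <- ape::write.tree(phy, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

## traversal helpers shared by engine and validation -----------------------

## edges ordered parents-before-children (preorder)
.preorder_edges <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  idx <- rev(seq_len(nrow(po$edge)))
  list(edge = po$edge[idx, , drop = FALSE],
       length = po$edge.length[idx])
}

## edges ordered children-before-parents (postorder)
.postorder_edges <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  list(edge = po$edge, length = po$edge.length)
}
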