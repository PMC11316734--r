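# Internal mutable tree structure used during seeding and growth.
# Implemented as an environment so incremental growth does not copy the
# whole state on every insertion. Node 1 is the root; `parent[i]` is the
# parent node of i (NA for the root); `rad[i]` is the radius (um) of the
# segment joining node i to its parent. Positions are mm.

tree_new <- function(root_pos, class = "artery", capacity = 256L) {
  tr <- new.env(parent = emptyenv())
  tr$pos <- matrix(NA_real_, capacity, 3)
  tr$pos[1, ] <- root_pos
  tr$parent <- rep(NA_integer_, capacity)
  tr$rad <- rep(NA_real_, capacity)
  tr$origin <- rep(NA_character_, capacity)
  tr$origin[1] <- "root"
  tr$frozen <- rep(FALSE, capacity)
  tr$anchor <- matrix(NA_real_, capacity, 3)  # nominal leaf positions
  tr$n <- 1L
  tr$class <- class
  tr
}

tree_reserve <- function(tr, k = 1L) {
  cap <- nrow(tr$pos)
  if (tr$n + k <= cap) return(invisible(tr))
  newcap <- max(cap * 2L, tr$n + k)
  pos <- matrix(NA_real_, newcap, 3); pos[1:tr$n, ] <- tr$pos[1:tr$n, ]
  tr$pos <- pos
  anc <- matrix(NA_real_, newcap, 3); anc[1:tr$n, ] <- tr$anchor[1:tr$n, ]
  tr$anchor <- anc
  tr$parent <- c(tr$parent, rep(NA_integer_, newcap - cap))
  tr$rad <- c(tr$rad, rep(NA_real_, newcap - cap))
  tr$origin <- c(tr$origin, rep(NA_character_, newcap - cap))
  tr$frozen <- c(tr$frozen, rep(FALSE, newcap - cap))
  invisible(tr)
}

tree_add_child <- function(tr, parent, pos, radius, origin = "growth") {
  tree_reserve(tr, 1L)
  i <- tr$n + 1L
  tr$pos[i, ] <- pos
  tr$parent[i] <- parent
  tr$rad[i] <- radius
  tr$origin[i] <- origin
  tr$n <- i
  i
}

tree_active <- function(tr) seq_len(tr$n)

# children of every node, as a list indexed by node
tree_children <- function(tr) {
  n <- tr$n
  ch <- vector("list", n)
  par <- tr$parent[seq_len(n)]
  for (i in seq_len(n)) {
    p <- par[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

tree_terminals <- function(tr) {
  n <- tr$n
  has_child <- rep(FALSE, n)
  par <- tr$parent[seq_len(n)]
  has_child[par[!is.na(par)]] <- TRUE
  which(!has_child & seq_len(n) != 1L)
}

tree_seg_lengths <- function(tr) {
  n <- tr$n
  par <- tr$parent[seq_len(n)]
  len <- rep(0, n)
  has <- which(!is.na(par))
  len[has] <- rownorms(tr$pos[has, , drop = FALSE] -
                       tr$pos[par[has], , drop = FALSE])
  len
}

# network cost sum(r^rho * l^lambda) over tree segments, r um, l um
tree_cost <- function(tr, rho = 1, lambda = 1) {
  n <- tr$n
  has <- which(!is.na(tr$parent[seq_len(n)]))
  len_um <- tree_seg_lengths(tr)[has] * UM_PER_MM
  sum(tr$rad[has]^rho * len_um^lambda)
}

# insert a node on the segment feeding `child`, at fraction t from the
# parent end; the new node inherits the segment radius. Returns its index.
tree_split_edge <- function(tr, child, t) {
  p <- tr$parent[child]
  stopifnot(!is.na(p), t >= 0, t <= 1)
  pos <- tr$pos[p, ] + t * (tr$pos[child, ] - tr$pos[p, ])
  i <- tree_add_child(tr, p, pos, tr$rad[child], origin = "split")
  tr$parent[child] <- i
  tr$frozen[i] <- tr$frozen[child]
  i
}

# Recompute the radius of the segment feeding `node` and all its ancestors
# from the Murray relation r_parent^gamma = sum(r_child^gamma); nodes with a
# single child are path continuations and inherit the child radius.
tree_murray_update <- function(tr, node, gamma) {
  ch <- tree_children(tr)
  j <- node
  while (!is.na(j)) {
    kids <- ch[[j]]
    if (length(kids) > 0)
      tr$rad[j] <- sum(tr$rad[kids]^gamma)^(1 / gamma)
    j <- tr$parent[j]
  }
  invisible(tr)
}

# Full bottom-up radius recomputation: leaves keep their radii, every
# internal segment carries the Murray composition of its children.
tree_recompute_radii <- function(tr, gamma) {
  n <- tr$n
  ch <- tree_children(tr)
  depth <- tree_depths(tr)
  ord <- order(depth, decreasing = TRUE)
  for (j in ord) {
    kids <- ch[[j]]
    if (length(kids) > 0)
      tr$rad[j] <- sum(tr$rad[kids]^gamma)^(1 / gamma)
  }
  invisible(tr)
}

tree_depths <- function(tr) {
  n <- tr$n
  par <- tr$parent[seq_len(n)]
  depth <- rep(NA_integer_, n)
  depth[1] <- 0L
  # nodes are appended after their parents, so one forward pass suffices
  for (i in seq_len(n)[-1]) depth[i] <- depth[par[i]] + 1L
  depth
}

tree_subtree <- function(tr, node) {
  n <- tr$n
  ch <- tree_children(tr)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    j <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, j)
    stack <- c(stack, ch[[j]])
  }
  out
}

# drop a set of nodes (must be subtree-closed, never the root), compacting
# indices; returns the tree invisibly
tree_drop_nodes <- function(tr, nodes) {
  if (length(nodes) == 0) return(invisible(tr))
  stopifnot(!1L %in% nodes)
  n <- tr$n
  keep <- setdiff(seq_len(n), nodes)
  map <- integer(n); map[keep] <- seq_along(keep)
  par <- tr$parent[keep]
  if (any(par %in% nodes))
    stop("tree_drop_nodes: node set is not subtree-closed")
  tr$pos[seq_along(keep), ] <- tr$pos[keep, , drop = FALSE]
  tr$anchor[seq_along(keep), ] <- tr$anchor[keep, , drop = FALSE]
  tr$parent[seq_along(keep)] <- ifelse(is.na(par), NA_integer_, map[par])
  tr$rad[seq_along(keep)] <- tr$rad[keep]
  tr$origin[seq_along(keep)] <- tr$origin[keep]
  tr$frozen[seq_along(keep)] <- tr$frozen[keep]
  tr$n <- length(keep)
  invisible(tr)
}

# scale all radii so the root segment radius equals `target` (um)
tree_rescale_root <- function(tr, target) {
  ch <- tree_children(tr)[[1]]
  stopifnot(length(ch) >= 1)
  f <- target / tr$rad[ch[1]]
  tr$rad[seq_len(tr$n)] <- tr$rad[seq_len(tr$n)] * f
  invisible(tr)
}

# Convert arterial and venous trees (plus optional extra capillary segments)
# into a vascular_network. Node ids: artery nodes first, then veins, then
# any capillary junction nodes. `capillaries` is a list of segments
# list(a = 3-vec | node ref, b = ..., radius) where a node ref is
# list(tree = "artery"|"vein", node = index).
trees_to_network <- function(artery, vein, capillaries = NULL,
                             metadata = list()) {
  build <- function(tr, offset, kind_root, class) {
    n <- tr$n
    ch <- tree_children(tr)
    nch <- lengths(ch)
    kind <- ifelse(seq_len(n) == 1L, kind_root,
            ifelse(nch == 0, "terminal",
            ifelse(nch == 1, "interior-path-point", "bifurcation")))
    nodes <- data.frame(id = offset + seq_len(n),
                        x = tr$pos[seq_len(n), 1], y = tr$pos[seq_len(n), 2],
                        z = tr$pos[seq_len(n), 3], kind = kind,
                        stringsAsFactors = FALSE)
    segs <- lapply(which(!is.na(tr$parent[seq_len(n)])), function(i) {
      p <- tr$parent[i]
      list(from = offset + p, to = offset + i,
           path = rbind(tr$pos[p, ], tr$pos[i, ]),
           radius = rep(tr$rad[i], 2), class = class)
    })
    list(nodes = nodes, segs = segs)
  }
  a <- build(artery, 0L, "inlet-root", "artery")
  v <- build(vein, nrow(a$nodes), "outlet-root", "vein")
  nodes <- rbind(a$nodes, v$nodes)
  segs <- c(a$segs, v$segs)
  if (!is.null(capillaries) && length(capillaries) > 0) {
    resolve <- function(endp) {
      if (is.list(endp)) {
        off <- if (endp$tree == "artery") 0L else artery$n
        id <- off + endp$node
        list(id = id, pos = as.numeric(nodes[id, c("x", "y", "z")]))
      } else {
        pos3 <- if (length(endp) == 2) c(endp, 0) else endp
        id <- nrow(nodes) + 1L
        nodes <<- rbind(nodes, data.frame(id = id, x = pos3[1], y = pos3[2],
                                          z = pos3[3], kind = "bifurcation",
                                          stringsAsFactors = FALSE))
        list(id = id, pos = pos3)
      }
    }
    # junction positions may repeat (shared capillary vertices): dedupe
    key_cache <- new.env(parent = emptyenv())
    resolve_cached <- function(endp) {
      if (is.list(endp)) return(resolve(endp))
      pos3 <- if (length(endp) == 2) c(endp, 0) else endp
      key <- paste(signif(pos3, 12), collapse = "_")
      hit <- key_cache[[key]]
      if (!is.null(hit)) return(hit)
      res <- resolve(endp)
      key_cache[[key]] <- res
      res
    }
    for (cs in capillaries) {
      e1 <- resolve_cached(cs$a); e2 <- resolve_cached(cs$b)
      if (e1$id == e2$id) next
      segs[[length(segs) + 1L]] <- list(from = e1$id, to = e2$id,
                                        path = rbind(e1$pos, e2$pos),
                                        radius = rep(cs$radius, 2),
                                        class = "capillary")
    }
  }
  for (i in seq_along(segs)) segs[[i]]$id <- i
  vascular_network(nodes, segs, inlet_id = 1L, outlet_id = artery$n + 1L,
                   metadata = metadata)
}
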