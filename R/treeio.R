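#' @title Dated trees with node ages and age-uncertainty intervals
#'
#' @description A `dated_tree` is an `ape` "phylo" tree augmented with per-node
#' point ages (Ma before present, larger = older) and optional 95% HPD
#' age intervals, as produced by Bayesian divergence dating. Node numbering
#' follows the `ape` convention: tips `1..n`, root `n+1`, further internal
#' nodes above that.
#'
#' @param phy an object of class "phylo" with branch lengths in Ma.
#' @param age numeric vector of node ages (Ma), indexed by node number. If
#'   missing, ages are computed from root-to-tip path lengths with the
#'   deepest tip at 0 Ma.
#' @param hpd two-column matrix `(older, younger)` of 95% HPD bounds per
#'   node, `NA` where absent.
#' @param clade_id label of the source clade or dataset.
#' @return an object of class `c("dated_tree", "phylo")`.
#' @export
dated_tree <- function(phy, age = NULL, hpd = NULL, clade_id = "clade") {
  if (!inherits(phy, "phylo")) .stopf("'phy' must be a phylo object")
  n_all <- length(phy$tip.label) + phy$Nnode
  if (is.null(age)) {
    if (is.null(phy$edge.length)) .stopf("branch lengths required to compute node ages")
    age <- .node_ages_from_lengths(phy)
  }
  if (length(age) != n_all) .stopf("'age' must have one entry per node (%d)", n_all)
  if (is.null(hpd)) hpd <- matrix(NA_real_, n_all, 2)
  hpd <- matrix(as.numeric(hpd), ncol = 2,
                dimnames = list(NULL, c("older", "younger")))
  if (nrow(hpd) != n_all) .stopf("'hpd' must have one row per node")
  phy$age <- as.numeric(age)
  phy$hpd <- hpd
  phy$clade_id <- clade_id
  class(phy) <- c("dated_tree", "phylo")
  validate_dated_tree(phy)
  phy
}

.node_ages_from_lengths <- function(phy) {
  n <- length(phy$tip.label)
  n_all <- n + phy$Nnode
  depth <- numeric(n_all)
  root <- n + 1L
  # preorder accumulation of depths
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    depth[ch] <- depth[p] + ord$edge.length[k]
  }
  age <- max(depth[seq_len(n)]) - depth
  age[abs(age) < 1e-9] <- 0  # zap roundoff at the present
  age
}

#' Validate a dated tree
#'
#' Checks the structural invariants: a single root, every internal node with
#' at least two children, age monotonicity along every edge (a parent is
#' never younger than its child), and ordered HPD bounds. HPD intervals that
#' exclude the point age are tolerated (pathological but seen in real
#' annotated trees) and flagged in the returned object.
#'
#' @param x a `dated_tree`.
#' @return `x`, invisibly, with a logical `hpd_excludes_age` component.
#' @export
validate_dated_tree <- function(x) {
  n <- length(x$tip.label)
  tab <- tabulate(x$edge[, 1], nbins = n + x$Nnode)
  internal <- (n + 1L):(n + x$Nnode)
  if (any(tab[internal] < 2))
    .stopf("internal node(s) with fewer than 2 children: %s",
           paste(internal[tab[internal] < 2], collapse = ", "))
  roots <- setdiff(x$edge[, 1], x$edge[, 2])
  if (length(unique(roots)) != 1) .stopf("tree must have exactly one root")
  bad <- x$age[x$edge[, 1]] - x$age[x$edge[, 2]] < -1e-9
  if (any(bad))
    .stopf("parent younger than child on edge(s): %s",
           paste(which(bad), collapse = ", "))
  has <- !is.na(x$hpd[, 1]) & !is.na(x$hpd[, 2])
  if (any(has & (x$hpd[, 1] - x$hpd[, 2] < -1e-12)))
    .stopf("HPD older bound < younger bound at node(s): %s",
           paste(which(has & (x$hpd[, 1] < x$hpd[, 2])), collapse = ", "))
  x$hpd_excludes_age <- has & (x$age > x$hpd[, 1] + 1e-9 | x$age < x$hpd[, 2] - 1e-9)
  invisible(x)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated tree '%s': %d tips, %d internal nodes, root age %.4g Ma\n",
              x$clade_id, length(x$tip.label), x$Nnode,
              x$age[length(x$tip.label) + 1L]))
  cat(sprintf("  HPD intervals on %d nodes\n", sum(!is.na(x$hpd[, 1]))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Newick / NEXUS parsing. A small recursive-descent parser is used instead of
# ape::read.tree because BEAST-style MCC trees carry node age HPDs in
# bracketed comments ([&height_95%_HPD={lo,hi}]) which standard readers drop.
# All other comment content is ignored, never an error.

.parse_newick <- function(text) {
  text <- gsub("[\r\n\t ]+", "", text)
  pos <- 1L
  nc <- nchar(text)
  peek <- function() if (pos <= nc) substr(text, pos, pos) else ""
  # node store
  labs <- character(); lens <- numeric(); comm <- character()
  kids <- list(); n_nodes <- 0L
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    labs[n_nodes] <<- ""; lens[n_nodes] <<- NA_real_; comm[n_nodes] <<- ""
    kids[[n_nodes]] <<- integer()
    n_nodes
  }
  take_comment <- function(id) {
    while (peek() == "[") {
      close <- regexpr("]", substr(text, pos, nc), fixed = TRUE)
      if (close < 0) .stopf("unterminated comment at char %d", pos)
      comm[id] <<- paste0(comm[id], substr(text, pos, pos + close - 1L))
      pos <<- pos + close
    }
  }
  read_label <- function() {
    if (peek() == "'") {
      end <- regexpr("'", substr(text, pos + 1L, nc), fixed = TRUE)
      if (end < 0) .stopf("unterminated quoted label at char %d", pos)
      lab <- substr(text, pos + 1L, pos + end - 1L)
      pos <<- pos + end + 1L
      return(lab)
    }
    m <- regexpr("^[^,():;\\[\\]]+", substr(text, pos, nc), perl = TRUE)
    if (m < 0 || attr(m, "match.length") == 0) return("")
    lab <- substr(text, pos, pos + attr(m, "match.length") - 1L)
    pos <<- pos + attr(m, "match.length")
    lab
  }
  parse_clade <- function() {
    id <- new_node()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids[[id]] <<- c(kids[[id]], parse_clade())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        .stopf("expected ',' or ')' at char %d ('%s')", pos, peek())
      }
      labs[id] <<- read_label()
    } else {
      labs[id] <<- read_label()
      if (labs[id] == "") .stopf("empty tip label at char %d", pos)
    }
    take_comment(id)
    if (peek() == ":") {
      pos <<- pos + 1L
      take_comment(id)  # branch-level comments (e.g. rate annotations)
      m <- regexpr("^[-+0-9.eE]+", substr(text, pos, nc))
      if (m < 0 || attr(m, "match.length") == 0)
        .stopf("expected branch length at char %d", pos)
      lens[id] <<- as.numeric(substr(text, pos, pos + attr(m, "match.length") - 1L))
      pos <<- pos + attr(m, "match.length")
      take_comment(id)
    }
    id
  }
  root <- parse_clade()
  if (peek() != ";") .stopf("expected ';' at char %d ('%s')", pos, peek())
  list(root = root, labs = labs, lens = lens, comm = comm, kids = kids,
       n = n_nodes)
}

.hpd_from_comment <- function(s) {
  m <- regmatches(s, regexpr("height_95%[_]?HPD=\\{[^}]*\\}", s, ignore.case = TRUE))
  if (length(m) == 0) return(c(NA_real_, NA_real_))
  vals <- as.numeric(strsplit(gsub(".*\\{|\\}", "", m[1]), ",")[[1]])
  if (length(vals) != 2 || any(is.na(vals))) return(c(NA_real_, NA_real_))
  c(max(vals), min(vals))  # (older, younger)
}

.tree_from_parse <- function(pt, clade_id) {
  is_tip <- lengths(pt$kids) == 0
  n_tip <- sum(is_tip)
  if (n_tip < 2) .stopf("tree must have at least 2 tips")
  if (any(!is.na(pt$lens) & pt$lens < 0)) .stopf("negative branch length")
  # map parser ids -> ape numbers: tips in parse order, internals in preorder
  num <- integer(pt$n)
  num[which(is_tip)] <- seq_len(n_tip)
  num[which(!is_tip)] <- n_tip + seq_len(sum(!is_tip))
  edge <- matrix(0L, pt$n - 1L, 2); el <- numeric(pt$n - 1L); k <- 0L
  walk <- function(id) {
    for (ch in pt$kids[[id]]) {
      k <<- k + 1L
      edge[k, ] <<- c(num[id], num[ch])
      if (is.na(pt$lens[ch]))
        .stopf("missing branch length above node '%s'", pt$labs[ch])
      el[k] <<- pt$lens[ch]
      walk(ch)
    }
  }
  walk(pt$root)
  phy <- list(edge = edge, edge.length = el,
              tip.label = pt$labs[which(is_tip)],
              Nnode = sum(!is_tip))
  nl <- pt$labs[which(!is_tip)]
  if (any(nzchar(nl))) phy$node.label <- nl
  class(phy) <- "phylo"
  hpd <- matrix(NA_real_, pt$n, 2)
  for (i in seq_len(pt$n)) if (nzchar(pt$comm[i]))
    hpd[num[i], ] <- .hpd_from_comment(pt$comm[i])
  dated_tree(phy, hpd = hpd, clade_id = clade_id)
}

#' Read a dated tree from newick or NEXUS
#'
#' Newick files must carry branch lengths in Ma; node ages are computed from
#' root-to-tip path lengths, placing the deepest tip at 0 Ma. NEXUS files in
#' the BEAST MCC dialect may carry bracketed node comments with
#' `height_95%_HPD={a,b}` annotations, which are attached as per-node age
#' HPD intervals; all other annotations are ignored.
#'
#' @param path file path.
#' @param format `"auto"` (default; NEXUS detected from the `#NEXUS` header),
#'   `"newick"`, or `"nexus"`.
#' @param clade_id clade label stored on the tree; defaults to the file name.
#' @return a [dated_tree].
#' @export
read_dated_tree <- function(path, format = c("auto", "newick", "nexus"),
                            clade_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (is.null(clade_id))
    clade_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("^#NEXUS", lines, ignore.case = TRUE))) "nexus" else "newick"
  if (format == "newick") {
    txt <- paste(lines, collapse = "")
    return(.tree_from_parse(.parse_newick(txt), clade_id))
  }
  .read_nexus_dated(lines, clade_id)
}

.read_nexus_dated <- function(lines, clade_id) {
  txt <- paste(lines, collapse = "\n")
  # translate table (optional): "Translate 1 taxonA, 2 taxonB, ... ;"
  tr_map <- NULL
  m <- regexpr("(?si)translate(.*?);", txt, perl = TRUE)
  if (m > 0) {
    body <- sub("(?i)^translate", "", regmatches(txt, m), perl = TRUE)
    body <- sub(";$", "", body)
    entries <- strsplit(body, ",")[[1]]
    entries <- trimws(gsub("[\r\n\t]+", " ", entries))
    entries <- entries[nzchar(entries)]
    key <- sub("^(\\S+)\\s+.*$", "\\1", entries)
    val <- sub("^\\S+\\s+(.*)$", "\\1", entries)
    val <- gsub("^'|'$", "", trimws(val))
    tr_map <- setNames(val, key)
  }
  tm <- regexpr("(?i)\\btree\\s+\\S+\\s*=\\s*", txt, perl = TRUE)
  if (tm < 0) .stopf("no tree statement found in NEXUS file")
  rest <- substr(txt, tm + attr(tm, "match.length"), nchar(txt))
  rest <- sub("^\\s*\\[&[RU]\\]\\s*", "", rest)
  semi <- regexpr(";", rest, fixed = TRUE)
  if (semi < 0) .stopf("unterminated tree statement in NEXUS file")
  tree_txt <- substr(rest, 1, semi)
  pt <- .parse_newick(gsub("[\r\n\t ]+", "", tree_txt))
  x <- .tree_from_parse(pt, clade_id)
  if (!is.null(tr_map)) {
    known <- x$tip.label %in% names(tr_map)
    x$tip.label[known] <- unname(tr_map[x$tip.label[known]])
  }
  x
}

#' Write a dated tree
#'
#' Writes newick with branch lengths at full precision; with
#' `hpd = TRUE`, nodes that carry age HPD intervals get a BEAST-style
#' bracketed `height_95%_HPD` comment so that [read_dated_tree()] round-trips
#' both ages and intervals.
#'
#' @param x a [dated_tree].
#' @param path output file path.
#' @param hpd write HPD node comments (default `TRUE`).
#' @param nexus wrap the tree in a minimal NEXUS trees block.
#' @return `path`, invisibly.
#' @export
write_dated_tree <- function(x, path, hpd = TRUE, nexus = FALSE) {
  n <- length(x$tip.label)
  children <- split(x$edge[, 2], factor(x$edge[, 1], levels = 1:(n + x$Nnode)))
  blen <- numeric(n + x$Nnode)
  blen[x$edge[, 2]] <- x$age[x$edge[, 1]] - x$age[x$edge[, 2]]
  fmt <- function(v) sprintf("%.12g", v)
  tag <- function(v) {
    if (hpd && !is.na(x$hpd[v, 1]))
      sprintf("[&height_95%%_HPD={%s,%s}]", fmt(x$hpd[v, 2]), fmt(x$hpd[v, 1]))
    else ""
  }
  rec <- function(v, root) {
    body <- if (v <= n) x$tip.label[v] else
      paste0("(", paste(vapply(children[[v]], rec, "", root = FALSE),
                        collapse = ","), ")")
    if (root) paste0(body, tag(v)) else paste0(body, tag(v), ":", fmt(blen[v]))
  }
  nw <- paste0(rec(n + 1L, TRUE), ";")
  out <- if (nexus) {
    c("#NEXUS", "Begin trees;", paste0("tree TREE1 = [&R] ", nw), "End;")
  } else nw
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Coding tables

#' Read a tip coding table
#'
#' Two-column delimited text (species, code); codes are strings over the
#' declared alphabet, with multi-area ranges written as concatenations (e.g.
#' `"AB"`). The delimiter (tab or comma) is auto-detected.
#'
#' @param path file path.
#' @param alphabet ordered vector of single-character state symbols.
#' @param scheme_id label for the coding scheme.
#' @return a data frame with columns `species` and `code`, class
#'   `"coding_table"`, carrying `alphabet` and `scheme_id` attributes.
#' @export
read_coding <- function(path, alphabet, scheme_id = "scheme") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE,
                   colClasses = "character", comment.char = "#",
                   strip.white = TRUE)
  if (ncol(df) < 2) .stopf("coding table needs two columns (species, code)")
  coding_table(setNames(df[[2]], df[[1]]), alphabet, scheme_id)
}

#' Build a coding table from a named vector of codes
#'
#' @param codes named character vector: species name -> code string.
#' @inheritParams read_coding
#' @return see [read_coding()].
#' @export
coding_table <- function(codes, alphabet, scheme_id = "scheme") {
  alphabet <- as.character(alphabet)
  if (any(nchar(alphabet) != 1)) .stopf("alphabet symbols must be single characters")
  sp <- names(codes)
  if (is.null(sp) || anyDuplicated(sp))
    .stopf("species names must be present and unique; duplicated: %s",
           paste(unique(sp[duplicated(sp)]), collapse = ", "))
  bad <- vapply(codes, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    length(ch) == 0 || !all(ch %in% alphabet)
  }, logical(1))
  if (any(bad))
    .stopf("code(s) outside alphabet {%s}: %s",
           paste(alphabet, collapse = ""),
           paste(sprintf("%s='%s'", sp[bad], codes[bad]), collapse = ", "))
  out <- data.frame(species = sp, code = unname(as.character(codes)),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  attr(out, "scheme_id") <- scheme_id
  class(out) <- c("coding_table", "data.frame")
  out
}

#' @export
#' @rdname read_coding
#' @param x a coding table.
write_coding <- function(x, path) {
  write.table(x[, c("species", "code")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Code string -> sorted vector of area symbols
.code_set <- function(code) sort(unique(strsplit(code, "")[[1]]))

# ---------------------------------------------------------------------------
# Event tables

.EVENT_TYPES <- c("dispersal_in", "in_situ")

#' Construct an event table
#'
#' An event table lists classified biogeographic events: dispersals into the
#' focal region (`dispersal_in`, anchored on the child node of the gaining
#' edge) and in situ diversification events (`in_situ`, anchored on the
#' diversifying node). Each event carries a point age and a closed age
#' interval `[older, younger]` in Ma; dispersal events may carry a source
#' region symbol.
#'
#' @param df data frame with columns `clade_id`, `event_type`, `node_id`,
#'   `point_age`, `older`, `younger`, `source_region`.
#' @return `df` with class `"event_table"`.
#' @export
event_table <- function(df = NULL) {
  cols <- c("clade_id", "event_type", "node_id", "point_age",
            "older", "younger", "source_region")
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(clade_id = character(), event_type = character(),
                     node_id = integer(), point_age = numeric(),
                     older = numeric(), younger = numeric(),
                     source_region = character(), stringsAsFactors = FALSE)
  }
  miss <- setdiff(cols, names(df))
  if (length(miss)) .stopf("event table missing column(s): %s",
                           paste(miss, collapse = ", "))
  df <- df[, cols]
  if (!all(df$event_type %in% .EVENT_TYPES))
    .stopf("event_type must be one of: %s", paste(.EVENT_TYPES, collapse = ", "))
  if (any(df$older - df$younger < -1e-12))
    .stopf("event interval with older < younger at row(s): %s",
           paste(which(df$older < df$younger), collapse = ", "))
  if (any(df$younger < -1e-12)) .stopf("negative event ages")
  if (any(nzchar(df$source_region) & df$event_type != "dispersal_in"))
    .stopf("source_region only allowed on dispersal_in events")
  key <- paste(df$clade_id, df$node_id, df$event_type)
  if (anyDuplicated(key))
    .stopf("duplicate (clade_id, node_id, event_type): %s",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read / write event tables
#'
#' Tab-delimited text with columns `clade_id`, `event_type`, `node_id`,
#' `point_age`, `older`, `younger`, `source_region`; lines starting with
#' `#` are treated as comments. `read_event_table(write_event_table(x))`
#' reproduces `x` exactly.
#'
#' @param x an [event_table].
#' @param path file path.
#' @param provenance optional character vector written as leading `#` lines.
#' @return the event table (read) or `path` invisibly (write).
#' @export
write_event_table <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  y <- x
  for (cc in c("point_age", "older", "younger"))
    y[[cc]] <- sprintf("%.12g", y[[cc]])
  write.table(y, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = c(clade_id = "character",
                                  event_type = "character",
                                  node_id = "integer",
                                  point_age = "numeric",
                                  older = "numeric", younger = "numeric",
                                  source_region = "character"))
  event_table(df)
}
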