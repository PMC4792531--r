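# Newick / NHX reader and writer.
#
# Recognised NHX tags: S= species (leaves) or taxon (internal nodes),
# D=Y|N duplication flag, DD=Y dubious-duplication flag, B= bootstrap,
# DCS= duplication confidence score, T= '+'-separated supporter tree ids.

#' Parse a Newick or NHX string
#'
#' @param text a single Newick string, terminated by `;`.
#' @param type `"gene"` (default) or `"species"`. For gene trees, leaf labels
#'   become gene ids and `S=` tags become species ids; for species trees all
#'   labels are taxon names.
#' @return a [gene_tree()] or [species_tree()].
#' @details A malformed string raises an error naming the offending character
#'   position. Numeric internal-node labels are additionally interpreted as
#'   bootstrap values (common Newick convention) unless a `B=` tag is present.
#' @export
parse_newick <- function(text, type = c("gene", "species")) {
  type <- match.arg(type)
  stopifnot(is.character(text), length(text) == 1L)
  src <- text
  nch <- nchar(src)
  pos <- 1L
  err <- function(msg) {
    stop(sprintf("Newick parse error at position %d: %s", pos, msg),
         call. = FALSE)
  }
  peek <- function() if (pos <= nch) substr(src, pos, pos) else ""
  skip_ws <- function() {
    while (pos <= nch && substr(src, pos, pos) %in% c(" ", "\t", "\n", "\r"))
      pos <<- pos + 1L
  }

  P <- integer(0); LEN <- numeric(0); LAB <- character(0)
  S_raw <- character(0); BT <- numeric(0); EV <- character(0)
  DCSV <- numeric(0); SUP <- list()

  new_node <- function(parent) {
    id <- length(P) + 1L
    P[id] <<- parent; LEN[id] <<- NA_real_; LAB[id] <<- ""
    S_raw[id] <<- NA_character_; BT[id] <<- NA_real_; EV[id] <<- NA_character_
    DCSV[id] <<- NA_real_; SUP[id] <<- list(NULL)
    id
  }

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      pos <<- pos + 1L
      start <- pos
      while (pos <= nch && substr(src, pos, pos) != "'") pos <<- pos + 1L
      if (pos > nch) err("unterminated quoted label")
      lab <- substr(src, start, pos - 1L)
      pos <<- pos + 1L
      return(lab)
    }
    start <- pos
    while (pos <= nch &&
           !substr(src, pos, pos) %in% c("(", ")", ",", ":", ";", "["))
      pos <<- pos + 1L
    trimws(substr(src, start, pos - 1L))
  }

  read_number <- function() {
    skip_ws()
    start <- pos
    while (pos <= nch && grepl("[-+0-9.eE]", substr(src, pos, pos)))
      pos <<- pos + 1L
    if (pos == start) err("expected a number")
    txt <- substr(src, start, pos - 1L)
    x <- suppressWarnings(as.numeric(txt))
    if (is.na(x)) err(sprintf("invalid number '%s'", txt))
    x
  }

  read_bracket <- function(id) {
    # pos is at '['
    rest <- substr(src, pos, nch)
    close <- regexpr("]", rest, fixed = TRUE)
    if (close < 0L) err("unterminated '[' comment")
    body <- substr(rest, 2L, close - 1L)
    pos <<- pos + close
    if (!startsWith(body, "&&NHX")) return(invisible(NULL))  # plain comment
    body <- sub("^&&NHX:?", "", body)
    if (!nzchar(body)) return(invisible(NULL))
    for (tag in strsplit(body, ":", fixed = TRUE)[[1L]]) {
      eq <- regexpr("=", tag, fixed = TRUE)
      if (eq < 0L) err(sprintf("malformed NHX tag '%s'", tag))
      key <- substr(tag, 1L, eq - 1L)
      val <- substr(tag, eq + 1L, nchar(tag))
      if (key == "S") S_raw[id] <<- val
      else if (key == "D") EV[id] <<- if (val == "Y") "duplication" else "speciation"
      else if (key == "DD" && val == "Y") EV[id] <<- "dubious"
      else if (key == "B") BT[id] <<- suppressWarnings(as.numeric(val))
      else if (key == "DCS") DCSV[id] <<- suppressWarnings(as.numeric(val))
      else if (key == "T") SUP[[id]] <<- strsplit(val, "+", fixed = TRUE)[[1L]]
      # unknown tags are ignored
    }
    invisible(NULL)
  }

  parse_subtree <- function(parent) {
    skip_ws()
    id <- new_node(parent)
    is_leaf <- peek() != "("
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_subtree(id)
        skip_ws()
        ch <- peek()
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        err("expected ',' or ')'")
      }
    }
    lab <- read_label()
    if (nzchar(lab)) LAB[id] <<- lab
    skip_ws()
    if (peek() == ":") { pos <<- pos + 1L; LEN[id] <<- read_number() }
    skip_ws()
    while (peek() == "[") { read_bracket(id); skip_ws() }
    if (is_leaf && !nzchar(LAB[id])) err("empty leaf label")
    id
  }

  parse_subtree(0L)
  skip_ws()
  if (peek() != ";") err("expected ';'")
  pos <- pos + 1L
  skip_ws()
  if (pos <= nch) err("trailing characters after ';'")

  children <- build_children(P)
  leaf <- lengths(children) == 0L
  if (type == "species") {
    lab <- LAB
    lab[!leaf & is.na(lab)] <- ""
    return(species_tree(parent = P, length = LEN, label = lab))
  }
  species <- ifelse(leaf, S_raw, NA_character_)
  taxon <- ifelse(!leaf, S_raw, NA_character_)
  # numeric internal labels are bootstrap values
  internal_num <- !leaf & is.na(BT) & grepl("^[0-9]+$", LAB)
  BT[internal_num] <- as.numeric(LAB[internal_num])
  gene_tree(parent = P, length = LEN, label = LAB,
            gene = ifelse(leaf, LAB, NA_character_), species = species,
            bootstrap = BT, event = EV, taxon = taxon, dcs = DCSV,
            supporters = SUP)
}

fmt_branch_length <- function(x) {
  if (is.na(x)) return("")
  s <- sprintf("%.9f", x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  paste0(":", s)
}

#' Serialize a tree to Newick / NHX
#'
#' @param tree a [gene_tree()] or [species_tree()].
#' @param nhx write NHX annotation tags (`S=`, `D=`, `DD=`, `B=`, `DCS=`,
#'   `T=`)? When `FALSE`, bootstrap values are emitted as plain internal-node
#'   labels so that standard Newick tools (e.g. ape) can read the output.
#' @param digits branch lengths are written with 9 decimal places and
#'   trailing zeros trimmed; the write/parse round trip is exact to 1e-9.
#' @return a single Newick string terminated by `;`.
#' @export
write_newick <- function(tree, nhx = TRUE, digits = 9) {
  is_sp <- inherits(tree, "species_tree")
  nhx_of <- function(v) {
    if (is_sp || !nhx) return("")
    tags <- character(0)
    leaf <- length(tree$children[[v]]) == 0L
    if (leaf && !is.na(tree$species[v]))
      tags <- c(tags, paste0("S=", tree$species[v]))
    if (!leaf && !is.na(tree$taxon[v]))
      tags <- c(tags, paste0("S=", tree$taxon[v]))
    ev <- tree$event[v]
    if (!is.na(ev)) {
      tags <- c(tags, paste0("D=", if (ev %in% c("duplication", "dubious")) "Y" else "N"))
      if (ev == "dubious") tags <- c(tags, "DD=Y")
    }
    if (!is.na(tree$bootstrap[v]))
      tags <- c(tags, paste0("B=", format(tree$bootstrap[v])))
    if (!is.na(tree$dcs[v]))
      tags <- c(tags, paste0("DCS=", sprintf("%.6g", tree$dcs[v])))
    if (length(tree$supporters[[v]]))
      tags <- c(tags, paste0("T=", paste(tree$supporters[[v]], collapse = "+")))
    if (!length(tags)) return("")
    paste0("[&&NHX:", paste(tags, collapse = ":"), "]")
  }
  rec <- function(v) {
    kids <- tree$children[[v]]
    if (!length(kids)) {
      core <- tree$label[v]
    } else {
      lab <- tree$label[v]
      if (!is_sp && !nhx && !is.na(tree$bootstrap[v]) && !nzchar(lab))
        lab <- format(tree$bootstrap[v])
      core <- paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
                     ")", lab)
    }
    paste0(core, fmt_branch_length(tree$length[v]), nhx_of(v))
  }
  paste0(rec(tree$root), ";")
}

#' Read a tree from a Newick/NHX file
#' @param path file containing a single Newick string.
#' @inheritParams parse_newick
#' @export
read_newick <- function(path, type = c("gene", "species")) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""), type = type)
}

#' Write a tree to a Newick/NHX file
#' @inheritParams write_newick
#' @param path output file.
#' @export
write_newick_file <- function(tree, path, nhx = TRUE) {
  writeLines(write_newick(tree, nhx = nhx), path)
  invisible(path)
}

# ---- ape interoperability ---------------------------------------------------

#' Convert to an ape "phylo" object (topology + branch lengths only)
#' @param tree a [gene_tree()] or [species_tree()].
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree, nhx = FALSE))
}

#' Convert an ape "phylo" object to a package tree
#' @param phy an `ape::phylo`.
#' @inheritParams parse_newick
#' @export
from_phylo <- function(phy, type = c("gene", "species")) {
  parse_newick(ape::write.tree(phy), type = match.arg(type))
}
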