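## Ranked taxonomy shared by the simulator and the classifier.

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Build a ranked taxonomy tree
#'
#' Constructs the six-rank hierarchy (domain, phylum, class, order, family,
#' genus) used both by the community simulator and by the rank-escalating
#' taxonomic classifier. The configuration is a data frame with one row per
#' genus and one column per rank (the `domain` column is optional and
#' defaults to `"Bacteria"`).
#'
#' @param config data.frame with columns `phylum`, `class`, `order`,
#'   `family`, `genus` (and optionally `domain`); one row per genus.
#' @return an object of class `taxonomy_tree`: a list with a `nodes` data
#'   frame (`id`, `name`, `rank`, `parent`) and the `root` id.
#' @examples
#' tree <- build_taxonomy(data.frame(
#'   phylum = "Firmicutes", class = "Clostridia", order = "Clostridiales",
#'   family = "Clostridiaceae", genus = "Clostridium"))
#' nrow(tree$nodes)
#' @export
build_taxonomy <- function(config) {
  config <- as.data.frame(config, stringsAsFactors = FALSE)
  if (!("domain" %in% names(config))) config$domain <- "Bacteria"
  need <- setdiff(TAX_RANKS, names(config))
  if (length(need)) stop("config lacks rank column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(config$genus))
    stop("duplicate genus name in configuration: ",
         paste(unique(config$genus[duplicated(config$genus)]), collapse = ", "))

  nodes <- data.frame(id = integer(0), name = character(0),
                      rank = character(0), parent = integer(0))
  key <- character(0)  # rank-qualified path key -> node id
  add_node <- function(name, rank, parent) {
    k <- paste(rank, name, sep = ":")
    hit <- match(k, key)
    if (!is.na(hit)) {
      id <- nodes$id[hit]
      if (nodes$parent[hit] != parent)
        stop("name '", name, "' reused within rank '", rank,
             "' under different parents")
      return(id)
    }
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, name, rank, parent)
    key[id] <<- k
    id
  }
  for (i in seq_len(nrow(config))) {
    parent <- 0L
    for (r in TAX_RANKS) {
      parent <- add_node(config[[r]][i], r, parent)
    }
  }
  if (sum(nodes$parent == 0L) != 1L)
    stop("configuration implies more than one root domain")
  if (length(unique(config$phylum)) < 1L || nrow(config) < 1L)
    stop("config must list at least one phylum with at least one genus")
  structure(list(nodes = nodes, root = nodes$id[nodes$parent == 0L]),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  n <- table(factor(x$nodes$rank, levels = TAX_RANKS))
  cat("taxonomy_tree:", paste(n, names(n), collapse = ", "), "\n")
  invisible(x)
}

#' Ancestor name of a genus at a given rank
#'
#' @param tree a `taxonomy_tree`.
#' @param genus genus name.
#' @param rank target rank.
#' @return the ancestor's name at `rank`.
#' @export
tax_ancestor <- function(tree, genus, rank) {
  nd <- tree$nodes
  i <- which(nd$name == genus & nd$rank == "genus")
  if (!length(i)) stop("genus not in taxonomy: ", genus)
  i <- i[1]
  while (nd$rank[i] != rank) {
    i <- match(nd$parent[i], nd$id)
    if (is.na(i)) stop("rank not on path: ", rank)
  }
  nd$name[i]
}

#' Full lineage of a genus
#'
#' @param tree a `taxonomy_tree`.
#' @param genus genus name.
#' @return named character vector, one name per rank.
#' @export
tax_lineage <- function(tree, genus) {
  vapply(TAX_RANKS, function(r) tax_ancestor(tree, genus, r), character(1))
}

tax_genera <- function(tree) tree$nodes$name[tree$nodes$rank == "genus"]

#' Default taxonomy of the emulated cellulose-rich community
#'
#' Seven genera spanning four phyla: the six dominant genera of the
#' emulated alkaline paper-pulp niche (two Bacteroidetes, three Firmicutes,
#' one Proteobacteria) plus one minor Actinobacteria genus.
#'
#' @return a `taxonomy_tree`.
#' @export
default_taxonomy <- function() build_taxonomy(default_taxonomy_config())

default_taxonomy_config <- function() {
  data.frame(
    phylum = c("Bacteroidetes", "Bacteroidetes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Proteobacteria", "Actinobacteria"),
    class  = c("Flavobacteriia", "Bacteroidia", "Bacilli", "Clostridia",
               "Clostridia", "Gammaproteobacteria", "Actinomycetia"),
    order  = c("Flavobacteriales", "Bacteroidales", "Bacillales",
               "Clostridiales", "Clostridiales", "Aeromonadales",
               "Micrococcales"),
    family = c("Weeksellaceae", "Dysgonomonadaceae", "Bacillaceae",
               "Clostridiaceae", "Acetivibrionaceae", "Aeromonadaceae",
               "Microbacteriaceae"),
    genus  = c("Cloacibacterium", "Paludibacter", "Exiguobacterium",
               "Clostridium", "Acetivibrio", "Tolumonas", "Microbacterium"),
    stringsAsFactors = FALSE)
}
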