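# GEXF 1.2 export for visualization in Gephi, plus a reader used for
# round-trip verification.

gexf_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

#' Export a co-occurrence network as GEXF 1.2
#'
#' Writes an undirected GEXF graph with node attributes (phylum, module,
#' degree, weighted_degree, closeness, betweenness, clustering) and edge
#' weights (= |rho|). Numeric attributes are written with enough digits to
#' round-trip to at least 6 significant figures.
#'
#' @param g a co-occurrence network.
#' @param path output `.gexf` file.
#' @param partition optional `module_partition` providing module ids.
#' @return `path`, invisibly.
#' @export
export_gexf <- function(g, path, partition = NULL) {
  stopifnot(igraph::is_igraph(g))
  nm <- node_metrics(g, partition)
  if (is.null(nm$module)) nm$module <- rep(NA_integer_, nrow(nm))
  if (is.null(nm$phylum)) nm$phylum <- rep("Unclassified", nrow(nm))
  num <- function(v) formatC(v, digits = 10, format = "g")
  attr_defs <- paste(
    '      <attribute id="0" title="phylum" type="string"/>',
    '      <attribute id="1" title="module" type="integer"/>',
    '      <attribute id="2" title="degree" type="integer"/>',
    '      <attribute id="3" title="weighted_degree" type="double"/>',
    '      <attribute id="4" title="closeness" type="double"/>',
    '      <attribute id="5" title="betweenness" type="double"/>',
    '      <attribute id="6" title="clustering" type="double"/>',
    sep = "\n")
  node_xml <- vapply(seq_len(nrow(nm)), function(i) {
    paste0(
      '      <node id="', gexf_escape(nm$taxon[i]), '" label="',
      gexf_escape(nm$taxon[i]), '">\n',
      "        <attvalues>\n",
      '          <attvalue for="0" value="', gexf_escape(nm$phylum[i]), '"/>\n',
      if (!is.na(nm$module[i]))
        paste0('          <attvalue for="1" value="', nm$module[i], '"/>\n')
      else "",
      '          <attvalue for="2" value="', nm$degree[i], '"/>\n',
      '          <attvalue for="3" value="', num(nm$weighted_degree[i]), '"/>\n',
      '          <attvalue for="4" value="', num(nm$closeness[i]), '"/>\n',
      '          <attvalue for="5" value="', num(nm$betweenness[i]), '"/>\n',
      '          <attvalue for="6" value="', num(nm$clustering[i]), '"/>\n',
      "        </attvalues>\n",
      "      </node>")
  }, character(1))
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- if (igraph::ecount(g) && !is.null(igraph::E(g)$weight))
    igraph::E(g)$weight else rep(1, igraph::ecount(g))
  edge_xml <- if (nrow(el)) vapply(seq_len(nrow(el)), function(k) {
    paste0('      <edge id="', k - 1L, '" source="', gexf_escape(el[k, 1L]),
           '" target="', gexf_escape(el[k, 2L]), '" weight="', num(w[k]), '"/>')
  }, character(1)) else character(0)
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">\n',
    '  <graph mode="static" defaultedgetype="undirected">\n',
    '    <attributes class="node">\n', attr_defs, "\n    </attributes>\n",
    "    <nodes>\n", paste(node_xml, collapse = "\n"),
    if (length(node_xml)) "\n" else "", "    </nodes>\n",
    "    <edges>\n", paste(edge_xml, collapse = "\n"),
    if (length(edge_xml)) "\n" else "", "    </edges>\n",
    "  </graph>\n</gexf>\n")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(xml, con, sep = "")
  invisible(path)
}

#' Read a GEXF file back into tables
#'
#' Companion to [export_gexf()], mainly for round-trip verification.
#'
#' @param path a `.gexf` file.
#' @return list with `nodes` (id plus declared attributes) and `edges`
#'   (source, target, weight).
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = xml2::xml_ns(doc)[[1]])
  adefs <- xml2::xml_find_all(doc, ".//g:attributes[@class='node']/g:attribute", ns)
  titles <- stats::setNames(xml2::xml_attr(adefs, "title"),
                            xml2::xml_attr(adefs, "id"))
  types <- stats::setNames(xml2::xml_attr(adefs, "type"),
                           xml2::xml_attr(adefs, "id"))
  node_nodes <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  nodes <- data.frame(id = xml2::xml_attr(node_nodes, "id"),
                      stringsAsFactors = FALSE)
  for (aid in names(titles)) {
    vals <- vapply(node_nodes, function(nd) {
      av <- xml2::xml_find_first(
        nd, sprintf(".//g:attvalue[@for='%s']", aid), ns)
      if (inherits(av, "xml_missing")) NA_character_
      else xml2::xml_attr(av, "value")
    }, character(1))
    nodes[[titles[[aid]]]] <-
      if (types[[aid]] %in% c("double", "integer", "float", "long"))
        as.numeric(vals) else vals
  }
  edge_nodes <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  edges <- data.frame(
    source = xml2::xml_attr(edge_nodes, "source"),
    target = xml2::xml_attr(edge_nodes, "target"),
    weight = as.numeric(xml2::xml_attr(edge_nodes, "weight")),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
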