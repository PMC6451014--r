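#' Export an overlay scene
#'
#' `"json"` writes one machine-readable, schema-versioned document that
#' [read_scene()] restores exactly. `"tsv_bundle"` writes `points.tsv`
#' (one row per tree node, leaves and internal), `edges.tsv` and
#' `groups.tsv` next to each other. `"html3d"` writes a single
#' self-contained HTML page with a drag-to-rotate 3D view of the scene,
#' using the package's color convention (blue monofunctional/slow, red
#' bifunctional/fast edge classes).
#'
#' @param scene an [overlay_tree()] scene.
#' @param path output file (for `tsv_bundle`: directory).
#' @param format `"json"`, `"tsv_bundle"` or `"html3d"`.
#' @export
export_scene <- function(scene, path,
                         format = c("json", "tsv_bundle", "html3d")) {
  format <- match.arg(format)
  stopifnot(inherits(scene, "overlay_scene"))
  if (format == "json") {
    doc <- list(schema_version = scene$provenance$schema_version %||% "1.0",
                provenance = scene$provenance,
                nodes = scene$nodes, edges = scene$edges)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns", na = "null", pretty = TRUE)
    return(invisible(path))
  }
  if (format == "tsv_bundle") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    write.table(scene$nodes, file.path(path, "points.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(scene$edges, file.path(path, "edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    leaves <- scene$nodes[scene$nodes$type == "leaf", ]
    grp <- if (all(is.na(leaves$group)))
      data.frame(group = "all", color = "grey30", n = nrow(leaves))
    else stats::aggregate(list(n = leaves$id),
                          by = list(group = leaves$group,
                                    color = leaves$color), length)
    write.table(grp[, c("group", "color", "n")],
                file.path(path, "groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  # html3d: self-contained canvas viewer around the scene JSON
  json <- jsonlite::toJSON(list(nodes = scene$nodes, edges = scene$edges),
                           auto_unbox = TRUE, digits = I(17),
                           dataframe = "columns", na = "null")
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>protspace sequence space</title>",
    "<style>body{font-family:sans-serif}canvas{border:1px solid #ccc}</style>",
    "</head><body>",
    "<h3>Sequence space (drag to rotate)</h3>",
    "<canvas id='c' width='800' height='600'></canvas>",
    paste0("<script>var scene=", json, ";"),
    "var cv=document.getElementById('c'),cx=cv.getContext('2d');",
    "var N=scene.nodes,E=scene.edges;",
    "var xs=N.x,ys=N.y,zs=N.z||N.x.map(function(){return 0;});",
    "var mx=avg(xs),my=avg(ys),mz=avg(zs);",
    "function avg(a){return a.reduce(function(p,q){return p+q},0)/a.length}",
    "var sc=250/Math.max.apply(null,xs.map(function(v,i){",
    "  return Math.sqrt((v-mx)*(v-mx)+(ys[i]-my)*(ys[i]-my)+(zs[i]-mz)*(zs[i]-mz))}));",
    "var ax=0,ay=0,drag=false,px,py;",
    "cv.onmousedown=function(e){drag=true;px=e.clientX;py=e.clientY};",
    "window.onmouseup=function(){drag=false};",
    "window.onmousemove=function(e){if(!drag)return;",
    "  ay+=(e.clientX-px)*0.01;ax+=(e.clientY-py)*0.01;px=e.clientX;py=e.clientY;draw()};",
    "function proj(i){var x=(xs[i]-mx)*sc,y=(ys[i]-my)*sc,z=(zs[i]-mz)*sc;",
    "  var x1=x*Math.cos(ay)+z*Math.sin(ay),z1=-x*Math.sin(ay)+z*Math.cos(ay);",
    "  var y1=y*Math.cos(ax)-z1*Math.sin(ax);",
    "  return [400+x1,300+y1]}",
    "function draw(){cx.clearRect(0,0,800,600);",
    "  var idx={};N.id.forEach(function(d,i){idx[d]=i});",
    "  cx.strokeStyle='#999';",
    "  for(var e=0;e<E.from.length;e++){var a=proj(idx[E.from[e]]),b=proj(idx[E.to[e]]);",
    "    cx.beginPath();cx.moveTo(a[0],a[1]);cx.lineTo(b[0],b[1]);cx.stroke()}",
    "  for(var i=0;i<N.id.length;i++){if(N.type[i]!=='leaf')continue;",
    "    var p=proj(i);cx.fillStyle=N.color[i]||'black';",
    "    cx.beginPath();cx.arc(p[0],p[1],4,0,7);cx.fill();",
    "    cx.fillStyle='#333';cx.fillText(N.label[i],p[0]+5,p[1]-5)}}",
    "draw();</script></body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Read a scene JSON document back
#'
#' @param path a file written by [export_scene()] with `format = "json"`.
#' @return an `overlay_scene`.
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) ps_stop("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version))
    ps_stop("not a protspace scene document")
  nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(doc$edges, stringsAsFactors = FALSE)
  # all-NA columns come back logical from JSON; restore declared types
  for (cn in intersect(c("x", "y", "z"), names(nodes)))
    nodes[[cn]] <- as.numeric(nodes[[cn]])
  nodes$saturated <- as.logical(nodes$saturated)
  nodes$group <- as.character(nodes$group)
  edges$length <- as.numeric(edges$length)
  edges$support <- as.numeric(edges$support)
  structure(list(nodes = nodes, edges = edges,
                 provenance = doc$provenance),
            class = "overlay_scene")
}
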