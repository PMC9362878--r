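#' Build a serialisable visualisation spec from a cluster-flow graph
#'
#' The spec is a plain nested list with deterministic key order covering
#' everything an interactive front end needs: positioned nodes with hover
#' annotations, links with counts, proportions and per-overlay paint, an
#' overlay registry, the optional ternary co-expression dataset, and traced
#' stable paths. It serialises to versioned JSON via [export_json()] and
#' round-trips losslessly.
#'
#' Annotation and paint entries that are `NA` are omitted from the spec
#' rather than written as nulls.
#'
#' @param g A `sankey_graph`; laid out with defaults if no layout present.
#' @param ternary Optional [ternary_dataset()] result.
#' @param paths Optional [trace_paths()] result.
#' @return An object of class `viz_spec`.
#' @export
as_viz_spec <- function(g, ternary = NULL, paths = NULL) {
  stopifnot(inherits(g, "sankey_graph"))
  if (is.null(g$layout)) g <- layout_graph(g)
  ann <- g$node_annotations
  ann_fields <- setdiff(colnames(ann), "node_id")

  nodes <- lapply(seq_len(nrow(g$nodes)), function(i) {
    nd <- list(
      id = g$nodes$node_id[i],
      resolution = g$nodes$res_label[i],
      label = g$nodes$label[i],
      size = g$nodes$size[i],
      x = g$layout$x[i], y = g$layout$y[i],
      height = g$layout$height[i], order = g$layout$order[i]
    )
    if (length(ann_fields) > 0L) {
      a <- list()
      for (fld in ann_fields) {
        v <- ann[[fld]][match(nd$id, ann$node_id)]
        if (!is.na(v)) a[[fld]] <- v
      }
      if (length(a) > 0L) nd$annotations <- a
    }
    nd
  })

  links <- lapply(seq_len(nrow(g$flows)), function(i) {
    lk <- list(
      source = g$flows$source[i], target = g$flows$target[i],
      count = g$flows$count[i],
      forward_prop = g$flows$forward_prop[i],
      backward_prop = g$flows$backward_prop[i]
    )
    if (length(g$overlays) > 0L) {
      paint <- list()
      for (nm in names(g$overlays)) {
        ov <- g$overlays[[nm]]
        pos <- match(g$flows$flow_id[i], ov$flow_id)
        entry <- list(hex = ov$hex[pos])
        if (ov$type == "expression") {
          entry$value <- ov$value[pos]
        } else if (ov$type == "gep" && ov$defined[pos]) {
          entry$gep <- ov$gep[pos, ]
        }
        paint[[nm]] <- entry
      }
      lk$paint <- paint
    }
    lk
  })

  registry <- lapply(names(g$overlays), function(nm) {
    ov <- g$overlays[[nm]]
    reg <- list(name = nm, type = ov$type)
    if (ov$type == "expression") {
      reg$gene <- ov$gene; reg$colormap <- ov$colormap
      reg$scale <- ov$scale; reg$range <- ov$range
    } else {
      reg$genes <- ov$genes
    }
    reg
  })

  spec <- list(
    schema = "cellflows-viz", schema_version = 1L,
    n_cells = g$n_cells,
    resolutions = as.list(g$res_labels),
    nodes = nodes, links = links,
    overlays = registry
  )
  if (!is.null(ternary)) {
    spec$ternary <- list(
      genes = as.list(attr(ternary, "genes")),
      points = lapply(seq_len(nrow(ternary)), function(i) list(
        flow = paste(ternary$source[i], ternary$target[i], sep = "->"),
        gep = c(ternary$gep1[i], ternary$gep2[i], ternary$gep3[i]),
        count = ternary$count[i], size = ternary$size[i],
        hex = ternary$hex[i]
      ))
    )
  }
  if (!is.null(paths) && nrow(paths) > 0L) {
    spec$paths <- lapply(seq_len(nrow(paths)), function(i) list(
      path_id = paths$path_id[i], nodes = paths$nodes[i],
      n_columns = paths$n_columns[i], score = paths$score[i],
      core_size = paths$core_size[i]
    ))
  }
  structure(spec, class = "viz_spec")
}

#' Validate a visualisation spec
#'
#' Checks that every link endpoint names an existing node and every overlay
#' referenced by a link's paint map exists in the overlay registry.
#'
#' @param spec A `viz_spec` (from [as_viz_spec()] or [import_json()]).
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_viz_spec <- function(spec) {
  node_ids <- vapply(spec$nodes, function(nd) as.character(nd$id), "")
  reg <- vapply(spec$overlays, function(ov) as.character(ov$name), "")
  for (lk in spec$links) {
    if (!(lk$source %in% node_ids) || !(lk$target %in% node_ids)) {
      stop("link ", lk$source, "->", lk$target,
           " references a missing node")
    }
    for (nm in names(lk$paint)) {
      if (!nm %in% reg) stop("link paint references unregistered overlay '",
                             nm, "'")
    }
  }
  invisible(TRUE)
}

#' Export a cluster-flow graph (or spec) to versioned JSON
#'
#' Serialisation is deterministic: fixed key order, numbers at 15
#' significant digits (idempotent under export-import-export), no
#' NA-derived nulls. The file round-trips byte-identically through
#' [import_json()].
#'
#' @param x A `sankey_graph` or `viz_spec`.
#' @param out Output path.
#' @param ... For a graph input, passed to [as_viz_spec()] (`ternary`,
#'   `paths`).
#' @return `out`, invisibly.
#' @export
export_json <- function(x, out, ...) {
  spec <- if (inherits(x, "viz_spec")) x else as_viz_spec(x, ...)
  validate_viz_spec(spec)
  # pretty printing is avoided: atomic vectors and equivalent lists would
  # format differently and break export-import-export byte identity
  json <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  con <- file(out, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(json), "\n")), con)
  invisible(out)
}

#' Import a visualisation spec from JSON
#'
#' @param path Path to a file written by [export_json()].
#' @return A `viz_spec` object.
#' @export
import_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(spec$schema, "cellflows-viz")) {
    stop("not a cellflows visualisation spec: ", path)
  }
  structure(spec, class = "viz_spec")
}

#' Render a visualisation spec to a standalone HTML document
#'
#' Produces a single self-contained file: the spec is embedded as JSON and
#' drawn client-side as an SVG Sankey diagram with a linked ternary chart.
#' An overlay selector switches among the precomputed paints, and a slider
#' filters flows by mutual proportion at render time. Output is a pure
#' function of the spec (byte-identical across runs).
#'
#' @param spec A `viz_spec`; validated before anything is written.
#' @param out Output HTML path.
#' @param title Document title.
#' @return `out`, invisibly.
#' @export
render_html <- function(spec, out, title = "Multi-resolution cluster flows") {
  stopifnot(inherits(spec, "viz_spec"))
  validate_viz_spec(spec)
  json <- as.character(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE,
                                        digits = NA))
  html <- sub("__TITLE__", title, html_template(), fixed = TRUE)
  html <- sub("__SPEC__", json, html, fixed = TRUE)
  con <- file(out, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(html), con)
  invisible(out)
}

html_template <- function() {
  paste0('<!DOCTYPE html>
<html><head><meta charset="utf-8"><title>__TITLE__</title>
<style>
 body{font-family:sans-serif;margin:12px}
 #controls{margin-bottom:8px}
 .node rect{stroke:#333;stroke-width:0.5}
 .flow{fill:none;opacity:0.55}
 .flow:hover{opacity:0.9}
 text{font-size:10px}
 #wrap{display:flex;gap:24px;align-items:flex-start}
</style></head><body>
<h3>__TITLE__</h3>
<div id="controls">
 overlay: <select id="overlay"><option value="">(structure)</option></select>
 &nbsp; min mutual proportion:
 <input type="range" id="minprop" min="0" max="1" step="0.01" value="0">
 <span id="minpropval">0</span>
</div>
<div id="wrap"><svg id="sankey" width="760" height="520"></svg>
<svg id="ternary" width="340" height="320"></svg></div>
<script>
var SPEC = __SPEC__;
var W=760,H=520,NW=14;
function nodeById(id){for(var i=0;i<SPEC.nodes.length;i++)
  if(SPEC.nodes[i].id===id)return SPEC.nodes[i];return null;}
function hover(n){var s="id "+n.id+"\\nsize "+n.size;
  if(n.annotations)for(var k in n.annotations)s+="\\n"+k+" "+n.annotations[k];
  return s;}
function draw(){
 var svg=document.getElementById("sankey");svg.innerHTML="";
 var ov=document.getElementById("overlay").value;
 var minp=parseFloat(document.getElementById("minprop").value);
 document.getElementById("minpropval").textContent=minp.toFixed(2);
 var off={};
 SPEC.links.forEach(function(lk){
   var mp=Math.min(lk.forward_prop,lk.backward_prop);
   if(mp<minp)return;
   var s=nodeById(lk.source),t=nodeById(lk.target);
   var h0=lk.count/SPEC.n_cells*(H*0.9);
   var y0=s.y*H+(off[s.id]=off[s.id]||0);
   var y1=t.y*H+(off["in_"+t.id]=off["in_"+t.id]||0);
   off[s.id]+=h0;off["in_"+t.id]+=h0;
   var x0=s.x*(W-60)+30+NW,x1=t.x*(W-60)+30;
   var c=(ov&&lk.paint&&lk.paint[ov])?lk.paint[ov].hex:"#999";
   var p=document.createElementNS("http://www.w3.org/2000/svg","path");
   var mx=(x0+x1)/2;
   p.setAttribute("d","M"+x0+","+y0+" C"+mx+","+y0+" "+mx+","+y1+
     " "+x1+","+y1);
   p.setAttribute("class","flow");
   p.setAttribute("stroke",c);p.setAttribute("stroke-width",Math.max(1,h0));
   var ti=document.createElementNS("http://www.w3.org/2000/svg","title");
   ti.textContent=lk.source+" -> "+lk.target+" ("+lk.count+" cells)";
   p.appendChild(ti);svg.appendChild(p);
 });
 SPEC.nodes.forEach(function(n){
   var gEl=document.createElementNS("http://www.w3.org/2000/svg","g");
   gEl.setAttribute("class","node");
   var r=document.createElementNS("http://www.w3.org/2000/svg","rect");
   r.setAttribute("x",n.x*(W-60)+30);
   r.setAttribute("y",(n.y-n.height/2)*H);
   r.setAttribute("width",NW);r.setAttribute("height",Math.max(2,n.height*H));
   var fill="#8aa";
   if(n.annotations&&n.annotations.silhouette_norm!==undefined){
     var v=n.annotations.silhouette_norm;
     fill="rgb("+Math.round(255*(1-v))+","+Math.round(120+100*v)+",160)";}
   r.setAttribute("fill",fill);
   var ti=document.createElementNS("http://www.w3.org/2000/svg","title");
   ti.textContent=hover(n);r.appendChild(ti);gEl.appendChild(r);
   var tx=document.createElementNS("http://www.w3.org/2000/svg","text");
   tx.setAttribute("x",n.x*(W-60)+30+NW+2);tx.setAttribute("y",n.y*H+3);
   tx.textContent=n.id;gEl.appendChild(tx);
   svg.appendChild(gEl);
 });
 drawTernary();
}
function drawTernary(){
 var svg=document.getElementById("ternary");svg.innerHTML="";
 if(!SPEC.ternary)return;
 var cx=170,cy=170,R=140;
 var A=[cx,cy-R],B=[cx-R*0.866,cy+R/2],C=[cx+R*0.866,cy+R/2];
 var tri=document.createElementNS("http://www.w3.org/2000/svg","path");
 tri.setAttribute("d","M"+A+" L"+B+" L"+C+" Z");
 tri.setAttribute("fill","none");tri.setAttribute("stroke","#333");
 svg.appendChild(tri);
 var lbl=[[A[0],A[1]-6],[B[0]-4,B[1]+12],[C[0]+4,C[1]+12]];
 SPEC.ternary.genes.forEach(function(gn,i){
  var t=document.createElementNS("http://www.w3.org/2000/svg","text");
  t.setAttribute("x",lbl[i][0]);t.setAttribute("y",lbl[i][1]);
  t.setAttribute("text-anchor","middle");t.textContent=gn;
  svg.appendChild(t);});
 SPEC.ternary.points.forEach(function(pt){
  var g=pt.gep;
  var x=g[0]*A[0]+g[1]*B[0]+g[2]*C[0];
  var y=g[0]*A[1]+g[1]*B[1]+g[2]*C[1];
  var c=document.createElementNS("http://www.w3.org/2000/svg","circle");
  c.setAttribute("cx",x);c.setAttribute("cy",y);
  c.setAttribute("r",Math.max(1,pt.size/2));
  c.setAttribute("fill",pt.hex);c.setAttribute("fill-opacity","0.8");
  var ti=document.createElementNS("http://www.w3.org/2000/svg","title");
  ti.textContent=pt.flow+" ("+pt.count+" cells)";
  c.appendChild(ti);svg.appendChild(c);});
}
var sel=document.getElementById("overlay");
SPEC.overlays.forEach(function(ov){
 var o=document.createElement("option");o.value=ov.name;
 o.textContent=ov.name;sel.appendChild(o);});
if(SPEC.overlays.length>0)sel.value=SPEC.overlays[0].name;
sel.addEventListener("change",draw);
document.getElementById("minprop").addEventListener("input",draw);
draw();
</script></body></html>
')
}
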