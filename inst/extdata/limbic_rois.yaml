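# Plane ROIs delineating the limbic bundles, recorded as slice indices in
# Mori DTI atlas space. Each bundle is extracted with multi-ROI AND logic:
# a streamline belongs to the bundle iff it crosses every listed plane.
# The cgc_partition planes split the cingulate cingulum into
# anterior/middle/posterior parts at the corpus callosum's projections.
fornix:
  - {axis: coronal, slice: 150}
  - {axis: axial, slice: 108}
cgh:
  - {axis: axial, slice: 126}
  - {axis: coronal, slice: 125}
cgc:
  - {axis: axial, slice: 126}
  - {axis: coronal, slice: 183}
cgc_partition:
  posterior_plane: {axis: coronal, slice: 127}
  anterior_plane: {axis: coronal, slice: 162}
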