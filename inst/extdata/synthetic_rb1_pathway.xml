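<?xml version="1.0"?>
<!-- Synthetic KGML fixture: a hand-written pathway fragment around RB1.
     Not a KEGG release file; topology mirrors make_rb1_toy_network(). -->
<pathway name="path:synthetic_rb1" org="hsa" number="00000" title="synthetic RB1 fragment">
  <entry id="1" name="hsa:5925" type="gene"/>
  <entry id="2" name="hsa:1869 hsa:1870 hsa:1871" type="gene"/>
  <entry id="3" name="hsa:595" type="gene"/>
  <entry id="4" name="hsa:1019" type="gene"/>
  <entry id="5" name="hsa:1021" type="gene"/>
  <entry id="6" name="hsa:1026" type="gene"/>
  <entry id="7" name="hsa:1029" type="gene"/>
  <entry id="8" name="path:hsa04110" type="map"/>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="1" entry2="3" type="PPrel">
    <subtype name="binding/association" value="---"/>
  </relation>
  <relation entry1="1" entry2="4" type="PPrel">
    <subtype name="phosphorylation" value="+p"/>
  </relation>
  <relation entry1="1" entry2="5" type="PPrel">
    <subtype name="phosphorylation" value="+p"/>
  </relation>
  <relation entry1="3" entry2="6" type="PPrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="3" entry2="7" type="PPrel">
    <subtype name="inhibition" value="--|"/>
  </relation>
</pathway>
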