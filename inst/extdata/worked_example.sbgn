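<?xml version="1.0" encoding="UTF-8"?>
<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
  <map language="process description">
    <glyph id="a" class="macromolecule">
      <label text="a"/>
      <bbox x="10" y="10" w="60" h="30"/>
    </glyph>
    <glyph id="aP" class="macromolecule">
      <label text="a"/>
      <glyph id="aP.sv" class="state variable">
        <state value="P" variable="site"/>
        <bbox x="12" y="48" w="20" h="10"/>
      </glyph>
      <bbox x="10" y="50" w="60" h="30"/>
    </glyph>
    <glyph id="atp" class="simple chemical">
      <label text="atp"/>
      <bbox x="10" y="90" w="40" h="40"/>
    </glyph>
    <glyph id="adp" class="simple chemical">
      <label text="adp"/>
      <bbox x="10" y="140" w="40" h="40"/>
    </glyph>
    <glyph id="b" class="macromolecule">
      <label text="b"/>
      <bbox x="10" y="190" w="60" h="30"/>
    </glyph>
    <glyph id="c" class="complex">
      <label text="c"/>
      <glyph id="c.a" class="macromolecule">
        <label text="a"/>
        <bbox x="92" y="12" w="50" h="25"/>
      </glyph>
      <glyph id="c.b" class="macromolecule">
        <label text="b"/>
        <bbox x="92" y="40" w="50" h="25"/>
      </glyph>
      <bbox x="90" y="10" w="60" h="60"/>
    </glyph>
    <glyph id="m" class="macromolecule">
      <label text="m"/>
      <bbox x="90" y="90" w="60" h="30"/>
    </glyph>
    <glyph id="p" class="process">
      <bbox x="160" y="10" w="20" h="20"/>
      <port id="p.in" x="155" y="20"/>
      <port id="p.out" x="185" y="20"/>
    </glyph>
    <glyph id="q" class="association">
      <bbox x="160" y="60" w="20" h="20"/>
      <port id="q.in" x="155" y="70"/>
      <port id="q.out" x="185" y="70"/>
    </glyph>
    <arc id="ar1" class="consumption" source="a" target="p.in"/>
    <arc id="ar2" class="consumption" source="atp" target="p.in"/>
    <arc id="ar3" class="production" source="p.out" target="aP"/>
    <arc id="ar4" class="production" source="p.out" target="adp"/>
    <arc id="ar5" class="consumption" source="a" target="q.in"/>
    <arc id="ar6" class="consumption" source="b" target="q.in"/>
    <arc id="ar7" class="production" source="q.out" target="c"/>
    <arc id="ar8" class="stimulation" source="m" target="p"/>
  </map>
</sbgn>
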