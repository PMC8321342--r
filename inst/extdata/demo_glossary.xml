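<?xml version="1.0" encoding="UTF-8"?>
<ForceFieldGlossary Name="demo-mm3">
  <Rule element="C" sybyl="C.3" type="1"/>
  <Rule element="C" sybyl="C.2" type="2"/>
  <Rule element="C" sybyl="C.ar" type="2"/>
  <Rule element="C" sybyl="C.1" type="4"/>
  <Rule element="C" degree="4" type="1"/>
  <Rule element="H" type="5"/>
  <Rule element="O" sybyl="O.3" type="6"/>
  <Rule element="O" sybyl="O.2" type="7"/>
  <Rule element="O" type="6"/>
  <Rule element="N" sybyl="N.3" type="8"/>
  <Rule element="N" type="8"/>
  <Rule element="S" type="15"/>
  <Rule element="P" type="25"/>
  <Rule element="F" type="11"/>
  <Rule element="Cl" type="12"/>
  <Rule element="Br" type="13"/>
  <Rule element="I" type="14"/>
</ForceFieldGlossary>
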