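<?xml version="1.0" encoding="UTF-8"?>
<annotations>
  <version>1.1</version>
  <image id="0" name="example_hip.png" width="300" height="256">
    <polygon label="ilium" occluded="0" points="95.000,50.000;105.000,50.000;105.000,200.000;95.000,200.000"/>
    <polygon label="acetabulum" occluded="0" points="98.000,208.000;102.000,212.000;188.000,162.000;185.000,158.000"/>
    <polygon label="labrum" occluded="0" points="200.000,150.000;215.000,138.000;230.000,130.000;220.000,145.000"/>
    <points label="check_upper" occluded="0" points="100.000,50.000"/>
    <points label="triradiate" occluded="0" points="100.000,200.000"/>
    <points label="lower_ilium" occluded="0" points="100.000,210.000"/>
    <points label="bone_edge" occluded="0" points="186.603,160.000"/>
    <points label="labrum_end" occluded="0" points="229.450,130.000"/>
  </image>
</annotations>
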