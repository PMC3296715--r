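(((((((Dmel:5.4,(Dsim:2,Dsec:2)simsec:3.4)melsim:7.4,(Dyak:10.4,Dere:10.4)yakere:2.4)melsub:31.4,Dana:44.2)melgrp:10.7,Dper:54.9)melobs:7.3,Dwil:62.2)Soph:0.9,((Dvir:32.7,Dmoj:32.7)virmoj:9.6,Dgri:42.3)Drosub:20.8)DrosSoph:406.9,Agam:470)root;
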