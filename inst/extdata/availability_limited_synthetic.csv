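"source","role","shift","weekday","probability"
"bank","RN","early",1,0.41
"agency","RN","early",1,0.34
"bank","NA","early",1,0.45
"agency","NA","early",1,0.38
"bank","RN","late",1,0.37
"agency","RN","late",1,0.3
"bank","NA","late",1,0.42
"agency","NA","late",1,0.34
"bank","RN","night",1,0.27
"agency","RN","night",1,0.2
"bank","NA","night",1,0.32
"agency","NA","night",1,0.24
"bank","RN","early",2,0.41
"agency","RN","early",2,0.34
"bank","NA","early",2,0.45
"agency","NA","early",2,0.38
"bank","RN","late",2,0.37
"agency","RN","late",2,0.3
"bank","NA","late",2,0.42
"agency","NA","late",2,0.34
"bank","RN","night",2,0.27
"agency","RN","night",2,0.2
"bank","NA","night",2,0.32
"agency","NA","night",2,0.24
"bank","RN","early",3,0.41
"agency","RN","early",3,0.34
"bank","NA","early",3,0.45
"agency","NA","early",3,0.38
"bank","RN","late",3,0.37
"agency","RN","late",3,0.3
"bank","NA","late",3,0.42
"agency","NA","late",3,0.34
"bank","RN","night",3,0.27
"agency","RN","night",3,0.2
"bank","NA","night",3,0.32
"agency","NA","night",3,0.24
"bank","RN","early",4,0.41
"agency","RN","early",4,0.34
"bank","NA","early",4,0.45
"agency","NA","early",4,0.38
"bank","RN","late",4,0.37
"agency","RN","late",4,0.3
"bank","NA","late",4,0.42
"agency","NA","late",4,0.34
"bank","RN","night",4,0.27
"agency","RN","night",4,0.2
"bank","NA","night",4,0.32
"agency","NA","night",4,0.24
"bank","RN","early",5,0.39
"agency","RN","early",5,0.32
"bank","NA","early",5,0.44
"agency","NA","early",5,0.36
"bank","RN","late",5,0.35
"agency","RN","late",5,0.28
"bank","NA","late",5,0.4
"agency","NA","late",5,0.32
"bank","RN","night",5,0.25
"agency","RN","night",5,0.18
"bank","NA","night",5,0.3
"agency","NA","night",5,0.22
"bank","RN","early",6,0.33
"agency","RN","early",6,0.26
"bank","NA","early",6,0.38
"agency","NA","early",6,0.3
"bank","RN","late",6,0.29
"agency","RN","late",6,0.22
"bank","NA","late",6,0.34
"agency","NA","late",6,0.26
"bank","RN","night",6,0.19
"agency","RN","night",6,0.15
"bank","NA","night",6,0.24
"agency","NA","night",6,0.16
"bank","RN","early",7,0.3
"agency","RN","early",7,0.23
"bank","NA","early",7,0.35
"agency","NA","early",7,0.27
"bank","RN","late",7,0.26
"agency","RN","late",7,0.19
"bank","NA","late",7,0.31
"agency","NA","late",7,0.23
"bank","RN","night",7,0.16
"agency","RN","night",7,0.15
"bank","NA","night",7,0.21
"agency","NA","night",7,0.15
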