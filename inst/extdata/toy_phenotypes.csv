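env,line,rep,trait,count
Env1,L001,1,Trait1,2
Env1,L001,1,Trait2,3
Env1,L001,2,Trait1,3
Env1,L001,2,Trait2,0
Env1,L002,1,Trait1,0
Env1,L002,1,Trait2,4
Env1,L002,2,Trait1,5
Env1,L002,2,Trait2,2
Env1,L003,1,Trait1,0
Env1,L003,1,Trait2,1
Env1,L003,2,Trait1,2
Env1,L003,2,Trait2,2
Env1,L004,1,Trait1,3
Env1,L004,1,Trait2,3
Env1,L004,2,Trait1,2
Env1,L004,2,Trait2,4
Env1,L005,1,Trait1,2
Env1,L005,1,Trait2,2
Env1,L005,2,Trait1,2
Env1,L005,2,Trait2,0
Env1,L006,1,Trait1,2
Env1,L006,1,Trait2,1
Env1,L006,2,Trait1,2
Env1,L006,2,Trait2,2
Env2,L001,1,Trait1,0
Env2,L001,1,Trait2,2
Env2,L001,2,Trait1,0
Env2,L001,2,Trait2,0
Env2,L002,1,Trait1,1
Env2,L002,1,Trait2,3
Env2,L002,2,Trait1,3
Env2,L002,2,Trait2,2
Env2,L003,1,Trait1,2
Env2,L003,1,Trait2,1
Env2,L003,2,Trait1,2
Env2,L003,2,Trait2,1
Env2,L004,1,Trait1,4
Env2,L004,1,Trait2,2
Env2,L004,2,Trait1,0
Env2,L004,2,Trait2,1
Env2,L005,1,Trait1,1
Env2,L005,1,Trait2,1
Env2,L005,2,Trait1,0
Env2,L005,2,Trait2,0
Env2,L006,1,Trait1,1
Env2,L006,1,Trait2,1
Env2,L006,2,Trait1,4
Env2,L006,2,Trait2,1
Env3,L001,1,Trait1,1
Env3,L001,1,Trait2,0
Env3,L001,2,Trait1,0
Env3,L001,2,Trait2,0
Env3,L002,1,Trait1,3
Env3,L002,1,Trait2,2
Env3,L002,2,Trait1,1
Env3,L002,2,Trait2,3
Env3,L003,1,Trait1,1
Env3,L003,1,Trait2,2
Env3,L003,2,Trait1,3
Env3,L003,2,Trait2,3
Env3,L004,1,Trait1,3
Env3,L004,1,Trait2,4
Env3,L004,2,Trait1,4
Env3,L004,2,Trait2,4
Env3,L005,1,Trait1,2
Env3,L005,1,Trait2,0
Env3,L005,2,Trait1,2
Env3,L005,2,Trait2,1
Env3,L006,1,Trait1,4
Env3,L006,1,Trait2,2
Env3,L006,2,Trait1,5
Env3,L006,2,Trait2,2
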