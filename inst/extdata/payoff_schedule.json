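{"version":"original-1994-block-cycled-1","decks":{"A":[[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350],[100,-0],[100,-0],[100,-150],[100,-0],[100,-300],[100,-0],[100,-200],[100,-0],[100,-250],[100,-350]],"B":[[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-0],[100,-1250],[100,-0]],"C":[[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50],[50,-0],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-0],[50,-50],[50,-50]],"D":[[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-0],[50,-250]]}}
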