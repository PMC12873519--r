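(((sp003:0.3473042481,(sp008:0.1276275705,(sp011:0.05844123661,sp001:0.05844123661):0.06918633386):0.2196766776):0.628525812,((sp006:0.5046649557,(sp010:0.1968424348,sp002:0.1968424348):0.3078225209):0.2394136594,((sp012:0.02062792832,sp004:0.02062792832):0.4495796103,(sp009:0.05932028356,sp007:0.05932028356):0.4108872551):0.2738710765):0.231751445):0.02416993991,sp005:1);
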